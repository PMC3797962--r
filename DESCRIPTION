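Package: dmpsynergy
Title: Movement Primitives with Shared, Time-Shiftable Muscle Synergies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dynamic movement primitives whose stable attractor systems are
    modulated by linear combinations of learned, parametrized, time-shiftable
    synergies shared across tasks. Provides discrete (Gaussian) and rhythmic
    (von Mises) parametrized basis functions, phase and attractor dynamics,
    first-order muscle activation dynamics, three multi-task benchmark
    environments (point-mass via-point reaching, a planar five-link biped
    walker with phase resetting, and a simplified muscle-actuated planar arm),
    episodic policy search with a covariance matrix adaptation evolution
    strategy that learns task-specific mixing weights and shared synergy
    parameters simultaneously, and synthetic-pattern generation with
    least-squares coefficient recovery for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
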