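Package: nephroflux
Title: Steady-State Epithelial Transport Simulation of the Human Nephron
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multi-nephron, steady-state model of transporter-mediated
    solute and water transport along the tubules of a human kidney. Six
    representative nephron classes (one superficial, five juxtamedullary)
    are resolved segment by segment from the proximal convoluted tubule to
    the inner-medullary collecting duct, with an epithelial cell compartment
    solved at every axial position by a damped Newton method.  Flux laws
    cover Goldman-Hodgkin-Katz electrodiffusion, osmotic water transport
    with reflection coefficients and solvent drag, and saturable carrier
    kinetics for SGLT1/SGLT2, GLUT1/GLUT2, NHE3, NKCC2, NCC, KCC and the
    Na+/K+-ATPase.  Scenario layers reproduce sex-specific transporter
    expression, moderate and severe diabetes, and pharmacological SGLT2
    inhibition, and the reporting layer produces whole-kidney deliveries,
    segmental transport, urinary excretion and the macula-densa chloride
    signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
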