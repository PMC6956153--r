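Package: onlenspower
Title: On-Eye Optical Power Change of Soft Contact Lenses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates how the optical power of a soft contact lens changes
    when it conforms to the cornea. Reduces uniaxial tensile records of
    hydrogel strips to an elastic modulus, generates tri-curve spherical and
    toric lens geometries, conforms them to a rigid spherical corneal model
    under tear-film and eyelid pressures using a stiffness-weighted,
    arc-length-preserving surrogate solver, ray-traces the conformed and
    undeformed lenses in three dimensions to obtain the effective power
    change (EPC), and orchestrates factorial sweeps over material, power,
    lens type and diameter with the associated two-sample t-tests and
    Pearson correlations. A finite-element input-file writer is included for
    external contact solvers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
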