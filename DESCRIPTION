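Package: emcc
Title: Thermodynamics of Electromicrobiological Concentration Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the energetics of electromicrobiological concentration
    cells: a single redox couple running simultaneously forward and in
    reverse in two spatially separated, electrically connected compartments,
    powered purely by concentration differences. Computes reaction quotients,
    Gibbs free energy and cell potentials with a linear conductor potential
    loss, builds theoretical gradient scenarios (oxygen, sulfide, hydrogen)
    and electron-number by concentration-span feasibility envelopes, and
    processes sediment microsensor depth profiles (detection-limit flooring,
    subsurface filtering, plateau overrides, pH gap filling, grid alignment)
    into depth-resolved free-energy feasibility assessments. Includes a
    seeded synthetic microprofile generator emulating microsensor exports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
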