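Package: ciliaflow
Title: Immersed-Boundary Lattice-Boltzmann Simulation of Mucociliary Clearance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional immersed boundary-lattice Boltzmann (IB-LBM)
    simulator of mucociliary clearance in the airway surface liquid. Beating
    node-spring cilia, driven by prescribed virtual-cilium postures through
    penalty springs, pump a two-layer mucus: a Newtonian periciliary liquid
    and an Oldroyd-B viscoelastic mucus layer separated by an advected elastic
    membrane. Includes a D2Q9 BGK solver with Guo forcing, an upper-convected
    Maxwell stress solver, regularized-delta-function fluid-structure coupling,
    rigid circular particles with short-range repulsion, passive-tracer
    transport measurement, a viscoelastic Poiseuille validation benchmark, and
    parameter sweeps over mucus thickness, cilia density and metachronal phase
    difference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
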