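Package: alefem
Title: Moving-Mesh ALE Finite Elements for Coupled Bulk-Surface
    Reaction-Diffusion on Evolving Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A conservative arbitrary Lagrangian-Eulerian (ALE) finite element
    framework for coupled bulk-surface reaction-diffusion equations on evolving
    two-dimensional domains. Bulk meshes are moved by a Winslow-monitor moving
    mesh PDE and the boundary curve evolves under a prescribed normal velocity
    with monitor-driven tangential node redistribution, so that remeshing is
    rarely needed even for strongly deforming domains. Time integration uses a
    semi-implicit predictor, a Crank-Nicolson bulk step and a Crank-Nicolson
    surface correction, giving second-order accuracy in space and time. The
    framework is applied to a model of eukaryotic cell migration and chemotaxis
    in which a membrane-bound activator-inhibitor system drives pseudopod-based
    boundary motion while an extracellular ligand field interacts with membrane
    receptors through reversible binding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
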