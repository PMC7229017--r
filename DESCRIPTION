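Package: radcs
Title: Automatic Anatomical Coordinate-System Placement for the Radius
Version: 0.1.0
Authors@R: person("radcs", "maintainers", email = "radcs@example.org", role = c("aut", "cre"))
Description: Places an anatomical coordinate system on full or partial radius
    bone surface meshes using the principal axes of the vertex inertia tensor,
    the centroid of the distal segment, and the radial styloid. Provides mesh
    input/output (STL, PLY), rigid transforms, proximal clipping for systematic
    shortening experiments, rigid-pose error metrics with a y-x-z Euler
    decomposition, a parametric synthetic radius generator with known
    ground-truth frames, a stochastic simulator of manual (observer) placement,
    and the statistical evaluation used in method-comparison studies: linear
    mixed models with likelihood-ratio tests, exact Mann-Whitney and
    Ansari-Bradley tests, and two-way absolute-agreement intraclass
    correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
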