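Package: valvephantom
Title: Parametric Aortic Valve Phantoms, Pulsatile Flow Synthesis and 4D Flow Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and analysis toolkit for 3D-printable semilunar-valve flow
    phantoms. Generates watertight triangle meshes of a parametric aortic root
    (sinuses of Valsalva, sinotubular junction, ascending aorta, left
    ventricular outflow tract) and trileaflet valve from named anatomical
    dimensions and exports them as STL; models the pulsatile pump waveform and
    hydrostatic afterload of a flow-loop bench; synthesises time-resolved
    three-component phase-contrast velocity fields over the phantom lumen
    (with venc phase encoding, aliasing and noise) written as NIfTI; and
    quantifies through-plane flow waveforms, net and peak flow, regurgitant
    fraction, proximal-distal conservation, sinus vortex circulation and
    Runge-Kutta particle pathlines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
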