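Package: denoise4d
Title: True 4D Adaptive Image Denoising with Monomial Filter Banks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-tensor steered adaptive filtering for 4D (x, y, z, t)
    image volumes such as time-resolved cardiac CT. Builds lognormal-radial
    monomial and quadrature filter banks, estimates the local 4x4 structure
    tensor from 14 monomial filter responses, maps it to a control tensor
    without eigendecomposition via matrix polynomials, and reconstructs the
    denoised data as an adaptively weighted sum of one lowpass and ten
    directional highpass filter responses. Includes spatial (windowed kernel)
    and FFT (ideal frequency response) backends, normalized convolution for
    border handling, out-of-core slab processing with exact overlap margins,
    valid-region and cost calculators, synthetic phantoms with SNR metrics,
    and NIfTI-1 / raw volume input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
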