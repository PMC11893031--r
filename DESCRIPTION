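Package: mrconsole
Title: Virtual Low-Field MRI Console and Digital Data Path
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete digital data path for a low-field MRI console with a
    virtual scanner backend in place of measurement hardware. Compiles Pulseq
    v1.4 pulse sequences into interleaved 16-bit four-channel transmit
    waveforms with packed digital control bits, generates turbo-spin-echo,
    free-induction-decay and hardware-monitoring protocols, simulates the MR
    signal from isochromat phantoms (including electromagnetic interference
    scenarios on auxiliary sensing channels), and implements the gated
    receive chain: phase-reference separation, quadrature demodulation, FIR
    decimation, k-space sorting, EDITER interference mitigation, Fourier
    reconstruction, NEMA-style SNR estimation and FID-based system
    calibrations. Raw data can be exported with an ISMRMRD-style XML header.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    xml2,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
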