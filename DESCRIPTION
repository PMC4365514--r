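Package: aerophen
Title: Aerial Multi-Sensor Phenotyping of Maize Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for low-altitude aerial phenotyping of maize field trials
    with a multi-sensor camera array (RGB, blue+near-infrared, thermal
    infrared). Co-registers per-campaign sensor images into a common
    area-of-interest frame using circular fiducial markers, normalized
    cross-correlation refinement and a projective transform; segments plants
    from soil with a blue-band NDVI threshold plus a grey-intensity shade
    filter (or an HSB colour-space alternative for RGB); extracts per-plot
    traits (canopy cover, plot and plant NDVI, pixel-distribution skewness,
    canopy temperature and its difference to air temperature); and computes
    trial-level statistics (variance components and repeatability by plot
    size, Pearson correlations with significance codes, Tukey HSD genotype
    comparisons). Includes sensor-geometry arithmetic (instantaneous field of
    view, ground footprint, motion blur, survey throughput), weather-derived
    quantities (thermal time, saturation vapour pressure, vapour pressure
    deficit, leaf area index from specific leaf weight), and a seeded
    synthetic scene generator producing a split-plot trial with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
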