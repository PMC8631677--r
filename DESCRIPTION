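Package: belugabuzz
Title: Acoustic Detection of Beluga Feeding from Echolocation Click Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying foraging behavior of beluga whales
    (Delphinapterus leucas) from echolocation click trains recorded by
    animal-borne tags and moored passive acoustic instruments. Computes
    inter-click-interval (ICI) features of terminal buzzes (minICI, maxICI,
    ICI range, ICI increment range, slope), separates feeding from social
    buzzes with an unsupervised cluster sweep (partitioning around medoids
    and seven-linkage agglomerative clustering) validated by the
    Fowlkes-Mallows index, extracts threshold rules with a decision stump,
    applies a two-step minICI/ICIir threshold classifier to long-term
    mooring data, summarizes presence and feeding as detection positive
    hours and foraging positive minutes, and aligns feeding occurrence with
    anadromous fish run timing via a travel-time-lag convolution of weir
    counts. Includes seeded synthetic-data generators emulating the
    statistical structure of feeding and social buzzes, mooring detection
    streams, and salmon run seasons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    rpart,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
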