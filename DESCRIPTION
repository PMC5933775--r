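Package: kpdclear
Title: Kidney Paired Donation Clearing with a Binary Ant Lion Optimizer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for clearing kidney paired donation (KPD) pools.
    Builds compatibility matrices from donor-patient pair pools under ABO
    blood-group rules, simulates Saidman-style pools with
    sensitization-driven crossmatch failure, enumerates all exchange
    chains and cycles up to a length bound, and selects a node-disjoint
    set of exchanges maximizing total utility.  Solvers include a binary
    Ant Lion Optimizer with great-value-priority initialization, bit-flip
    mutation walks and a greedy post-processing repair stage, a
    genetic-algorithm baseline, and an exact branch-and-bound solver for
    the underlying weighted set-packing problem.  A round-based harness
    supports dynamic multi-round simulation and solver benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
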