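# shared fixtures, built once per test run
CONSENSUS_FILL <- "GYGSTQTAGEGSSLTA"

consensus_annotation <- local({
  cache <- new.env()
  function(n_coils = 8, numbering_start = 1L) {
    key <- paste(n_coils, numbering_start)
    if (is.null(cache[[key]])) {
      cache[[key]] <- detect_repeats(strrep(CONSENSUS_FILL, n_coils),
                                     numbering_start = numbering_start)
    }
    cache[[key]]
  }
})

consensus_model <- local({
  cache <- new.env()
  function(n_coils = 8, mode = "cbeta_only", handedness = "right") {
    key <- paste(n_coils, mode, handedness)
    if (is.null(cache[[key]])) {
      cache[[key]] <- build_helix(
        consensus_annotation(n_coils),
        helix_params(handedness = handedness, sidechain_mode = mode)
      )
    }
    cache[[key]]
  }
})

# independent dihedral computation for torsion oracles (kept separate from
# the package's own implementation)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  m1 <- cx(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

atom_xyz <- function(model, sel = rep(TRUE, nrow(model))) {
  unname(as.matrix(model[sel, c("x", "y", "z")]))
}
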