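# Small fixtures built in code.

make_toy_cm <- function() {
  m <- matrix(c(5L, 3L, 0L,
                2L, 0L, 7L,
                1L, 1L, 1L,
                0L, 4L, 2L), nrow = 4, byrow = TRUE,
              dimnames = list(c("S1", "S2", "N1", "S3"),
                              c("ASV1", "ASV2", "ASV3")))
  count_matrix(m, c(S1 = "GU", S2 = "GU", N1 = "NC", S3 = "GU"))
}

# counts with planted structure for QC rule checks: n_gu GU + n_nc NC samples
make_qc_cm <- function(presence_gu, presence_nc, n_gu = 100, n_nc = 10,
                       reads_present = 50L) {
  m <- matrix(0L, n_gu + n_nc, length(presence_gu),
              dimnames = list(c(sprintf("GU%03d", seq_len(n_gu)),
                                sprintf("NC%03d", seq_len(n_nc))),
                              sprintf("ASV%02d", seq_along(presence_gu))))
  for (j in seq_along(presence_gu)) {
    if (presence_gu[j] > 0) m[seq_len(presence_gu[j]), j] <- reads_present
    if (presence_nc[j] > 0) m[n_gu + seq_len(presence_nc[j]), j] <- reads_present
  }
  ## a common abundant ASV so no library is empty
  m <- cbind(m, FILLER = 1000L)
  count_matrix(m, setNames(c(rep("GU", n_gu), rep("NC", n_nc)), rownames(m)))
}

random_tree <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n_leaves, tip.label = sprintf("L%02d", seq_len(n_leaves)))
  tr$edge.length <- tr$edge.length + 0.01
  tr
}
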