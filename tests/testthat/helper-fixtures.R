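# shared fixtures and independent oracles, built in code

toy_counts <- function() {
  m <- matrix(c(10, 20, 5,
                20, 40, 10,
                30, 60, 15,
                8, 16, 4), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  storage.mode(m) <- "integer"
  m
}

# independent Benjamini-Hochberg oracle: per element, the minimum over all
# p_j >= p_i of m * p_j / #{k: p_k <= p_j}, capped at 1
brute_force_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    js <- which(p >= pi)
    min(1, min(vapply(p[js], function(pj) m * pj / sum(p <= pj), numeric(1))))
  }, numeric(1))
}

# independent method-of-moments dispersion on a raw count matrix with
# equal expected library sizes (no size-factor step)
mom_dispersion_oracle <- function(counts, iA, iB) {
  mA <- rowMeans(counts[, iA, drop = FALSE])
  mB <- rowMeans(counts[, iB, drop = FALSE])
  m <- rowMeans(counts)
  ss <- rowSums((counts[, iA, drop = FALSE] - mA)^2) +
    rowSums((counts[, iB, drop = FALSE] - mB)^2)
  s2 <- ss / (length(iA) + length(iB) - 2)
  pmax(0, (s2 - m) / m^2)
}

# a small annotation table matching toy_counts
toy_annotation <- function() {
  data.frame(gene_id = paste0("g", 1:4), symbol = paste0("Sym", 1:4),
             length_bp = c(1000L, 2000L, 500L, 1000L), family = "",
             stringsAsFactors = FALSE)
}
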