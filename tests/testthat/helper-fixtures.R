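# shared fixture builders for the test suite

default_grid <- function(protocol = gradient_protocol()) {
  n <- protocol$n_fractions
  w <- (protocol$bd_bottom - protocol$bd_top) / n
  hi <- protocol$bd_bottom - (seq_len(n) - 1) * w
  data.frame(fraction_index = seq_len(n), bd_lo = hi - w, bd_hi = hi,
             buoyant_density = hi - w / 2)
}

# a fraction_profile on the default 16-fraction grid from a copies vector
profile_from_copies <- function(copies, gene = "AOB", treatment = "15N-urea",
                                replicate = 1L) {
  grid <- default_grid()
  stopifnot(length(copies) == nrow(grid))
  fraction_profile(gene, treatment,
                   data.frame(fraction_index = grid$fraction_index,
                              buoyant_density = grid$buoyant_density,
                              copies = copies),
                   replicate = replicate)
}

# small Zotu table: 4 Zotus, HF and CK sample pairs
toy_zotu_table <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(50, 40, 5, 5,
                       60, 30, 5, 5,
                       10, 70, 10, 10,
                       12, 68, 10, 10),
                     nrow = 4, dimnames = list(
                       paste0("Zotu", 1:4),
                       c("HF_1", "HF_2", "CK_1", "CK_2")))
  }
  zotu_table(
    counts,
    samples = data.frame(sample = colnames(counts),
                         treatment = rep(c("15N-urea", "CK"), each = 2),
                         fraction_class = rep(c("HF", "light"), each = 2)),
    taxonomy = data.frame(zotu = rownames(counts),
                          gene = c("AOA", "AOA", "AOB", "AOB"),
                          clade = c("NS-Gamma", "NS-Alpha",
                                    "Nitrosospira", "Nitrosospira")))
}

# independent brute-force one-way ANOVA oracle (plain sums of squares)
anova_oracle <- function(groups) {
  y <- unlist(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(y)
  ssb <- sum(lengths(groups) * (means - grand)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  (ssb / df1) / (ssw / df2)
}
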