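#' Simulate CsCl gradient fractionation of labeled and unlabeled DNA
#'
#' Each taxon bands as a Gaussian over buoyant density with mean
#' `unlabeled_density(gc) + label_shift(atom15n, gc)` (the shift is applied
#' only under the 15N treatment) and standard deviation `band_sigma`. The
#' gradient is cut into `n_fractions` contiguous windows on a linear density
#' grid from `bd_bottom` (fraction 1, heaviest) to `bd_top`; the expected
#' copies in a window are the taxon's total copies times the Gaussian mass
#' in that window. Taxa sharing a marker gene are co-amplified: their
#' expected per-fraction copies are summed before multiplicative log-normal
#' qPCR noise (`10^e`, `e ~ N(0, qpcr_noise_sigma)`) is applied and readings
#' below `detection_floor` are zeroed.
#'
#' @param taxa a [taxon_spec()] or list of them.
#' @param protocol a [gradient_protocol()].
#' @param treatment `"15N"` (labeled urea; taxa band at their shifted
#'   density) or `"14N"` (unlabeled control; all shifts are zero).
#' @param seed integer seed; identical seeds give identical datasets.
#' @param soil soil label carried into the profiles.
#' @return A `gradient_dataset`: list with `profiles` (named list of
#'   [fraction_profile()], one per gene), `table` (long data.frame with
#'   columns gene, treatment, fraction_index, buoyant_density_g_ml,
#'   copies_per_g), `taxa`, `protocol`, `treatment`, `seed`.
#' @examples
#' tx <- taxon_spec("AOB", 1e7, gc = 0.5, atom15n = 1)
#' sim <- simulate_gradient(tx, gradient_protocol(), "15N", seed = 1)
#' peak_bd(sim$profiles[["amoA"]])
#' @export
simulate_gradient <- function(taxa, protocol = gradient_protocol(),
                              treatment = c("15N", "14N"), seed = NULL,
                              soil = NA_character_) {
  treatment <- match.arg(treatment)
  if (inherits(taxa, "taxon_spec")) taxa <- list(taxa)
  if (length(taxa) == 0) stop("at least one taxon required", call. = FALSE)
  stopifnot(all(vapply(taxa, inherits, logical(1), "taxon_spec")),
            inherits(protocol, "gradient_protocol"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  grid <- fraction_grid(protocol)
  genes <- unique(vapply(taxa, `[[`, character(1), "gene"))

  profiles <- list()
  rows <- list()
  for (g in genes) {
    expected <- numeric(protocol$n_fractions)
    for (tx in taxa) {
      if (tx$gene != g) next
      shift <- if (treatment == "15N") label_shift(tx$atom15n, tx$gc) else 0
      mu <- unlabeled_density(tx$gc) + shift
      mass <- pnorm(grid$bd_hi, mu, tx$band_sigma) -
        pnorm(grid$bd_lo, mu, tx$band_sigma)
      expected <- expected + tx$total_copies * mass
    }
    eps <- if (protocol$qpcr_noise_sigma > 0) {
      rnorm(protocol$n_fractions, 0, protocol$qpcr_noise_sigma)
    } else {
      numeric(protocol$n_fractions)
    }
    observed <- expected * 10^eps
    observed[observed < protocol$detection_floor] <- 0
    profiles[[g]] <- fraction_profile(
      gene = g, treatment = paste0(treatment, "-urea"),
      fractions = data.frame(fraction_index = grid$fraction_index,
                             buoyant_density = grid$buoyant_density,
                             copies = observed),
      soil = soil)
    rows[[g]] <- data.frame(gene = g, treatment = paste0(treatment, "-urea"),
                            fraction_index = grid$fraction_index,
                            buoyant_density_g_ml = grid$buoyant_density,
                            copies_per_g = observed)
  }
  structure(
    list(profiles = profiles, table = do.call(rbind, c(rows, make.row.names = FALSE)),
         taxa = taxa, protocol = protocol, treatment = treatment, seed = seed),
    class = "gradient_dataset"
  )
}

#' Simulate a paired 14N/15N SIP gradient experiment
#'
#' Runs [simulate_gradient()] under both treatments with independent noise
#' draws derived from one seed, on an identical fraction grid — the paired
#' design used to call heavy fractions by contrasting the 15N against the
#' 14N profile of the same gene.
#'
#' @inheritParams simulate_gradient
#' @return List with elements `label15N` and `label14N`, each a
#'   `gradient_dataset`.
#' @export
simulate_sip_experiment <- function(taxa, protocol = gradient_protocol(),
                                    seed = 1, soil = NA_character_) {
  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max, 2)
  list(
    label15N = simulate_gradient(taxa, protocol, "15N", seed = sub[1], soil = soil),
    label14N = simulate_gradient(taxa, protocol, "14N", seed = sub[2], soil = soil)
  )
}
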