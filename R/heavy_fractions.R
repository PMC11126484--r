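#' Identify heavy (15N-labeled) fractions from paired profiles
#'
#' Heavy fractions (HF) are the gradient fractions into which the DNA of an
#' active, 15N-incorporating population is displaced. They are called by
#' contrasting the max-normalized 15N-treatment profile against the
#' 14N-treatment control of the same gene: the HF set is the maximal
#' contiguous run of fractions, strictly on the heavy side of the 14N peak,
#' in which the normalized 15N signal exceeds the normalized 14N signal by
#' at least `margin`. The run must contain the 15N profile's own peak
#' fraction; otherwise no labeling is detected. A `manual_set` (e.g. the
#' fraction ranges read off a published profile figure) bypasses the rule
#' and is only validated against the grid.
#'
#' @param profile15 [fraction_profile()] from the 15N treatment.
#' @param profile14 matching profile from the 14N control; must share the
#'   fraction grid.
#' @param margin minimum normalized-signal excess (default 0.10).
#' @param manual_set optional integer vector of fraction indices to use
#'   verbatim.
#' @return Sorted integer vector of HF fraction indices; a zero-length
#'   integer vector means "no labeling detected" (this is a result, not an
#'   error).
#' @export
identify_heavy_fractions <- function(profile15, profile14, margin = 0.10,
                                     manual_set = NULL) {
  idx <- profile15$fraction_index
  if (!is.null(manual_set)) {
    manual_set <- sort(as.integer(manual_set))
    if (!all(manual_set %in% idx)) {
      stop("manual_set contains fraction indices outside the grid",
           call. = FALSE)
    }
    return(manual_set)
  }
  if (!isTRUE(all.equal(idx, profile14$fraction_index)) ||
      !isTRUE(all.equal(profile15$buoyant_density,
                        profile14$buoyant_density, tolerance = 1e-8))) {
    stop("profiles do not share a fraction grid", call. = FALSE)
  }
  n15 <- normalize_profile(profile15)
  n14 <- normalize_profile(profile14)

  bd <- profile15$buoyant_density
  bd_peak14 <- bd[peak_index_pos(profile14)]
  pos_peak15 <- peak_index_pos(profile15)

  qualifies <- (bd > bd_peak14) & (n15 - n14 >= margin)
  if (!qualifies[pos_peak15]) return(integer(0))

  # maximal contiguous run (in index order) containing the 15N peak
  r <- rle(qualifies)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  run <- which(r$values & starts <= pos_peak15 & ends >= pos_peak15)
  sort(as.integer(idx[seq(starts[run], ends[run])]))
}

#' Heavy-fraction ratio of a profile
#'
#' Ratio of raw gene copies in the heavy-fraction set to the sum over all
#' gradient fractions. Raw copies (not normalized values) are used, so the
#' ratio is invariant under uniform rescaling of the profile.
#'
#' @param profile a [fraction_profile()] with positive total copies.
#' @param hf_set integer vector of heavy-fraction indices (non-empty, a
#'   subset of the profile's fractions).
#' @return Ratio in \[0, 1\].
#' @export
hf_ratio <- function(profile, hf_set) {
  if (length(hf_set) == 0) stop("hf_set is empty", call. = FALSE)
  hf_set <- as.integer(hf_set)
  if (!all(hf_set %in% profile$fraction_index)) {
    stop("hf_set contains fraction indices outside the profile", call. = FALSE)
  }
  total <- sum(profile$copies)
  if (total <= 0) stop("profile has zero total copies", call. = FALSE)
  sum(profile$copies[profile$fraction_index %in% hf_set]) / total
}

#' 15N-labeled gene abundance
#'
#' The labeled abundance is the heavy-fraction ratio applied to the gene's
#' total abundance in unfractionated (total) DNA: `A_label = R * A_total`,
#' in copies per g dry soil.
#'
#' @param hf_ratio heavy-fraction ratio(s) in \[0, 1\].
#' @param total_abundance total gene abundance, copies/g dry soil (>= 0).
#' @return Labeled abundance, copies/g dry soil; never exceeds
#'   `total_abundance`.
#' @examples
#' labeled_abundance(0.930, 14.4e7) # ~1.34e8 copies/g
#' @export
labeled_abundance <- function(hf_ratio, total_abundance) {
  check_fraction(hf_ratio, "hf_ratio")
  if (any(total_abundance < 0)) {
    stop("total_abundance must be >= 0", call. = FALSE)
  }
  hf_ratio * total_abundance
}

#' Quantify 15N labeling for replicated paired profiles
#'
#' Full SIP quantification for one gene: heavy fractions are detected on the
#' replicate-mean normalized profiles (or taken from `manual_set`), then the
#' HF ratio and labeled abundance are computed per replicate and averaged;
#' mean and standard error are reported.
#'
#' @param profiles15 list of 15N-treatment [fraction_profile()]s (one per
#'   replicate), or a single profile.
#' @param profiles14 matching list of 14N-control profiles.
#' @param total_abundance per-replicate total gene abundance (copies/g) in
#'   total DNA; recycled if scalar.
#' @param margin,manual_set passed to [identify_heavy_fractions()].
#' @return A one-row data.frame of class `labeling_estimate`: gene, n_reps,
#'   hf_fractions (dash-separated), hf_ratio, hf_ratio_se, total_abundance,
#'   labeled_abundance, labeled_abundance_se, peak_bd_15N, peak_bd_14N,
#'   labeled (logical). When no labeling is detected the ratio and labeled
#'   abundance are NA and `labeled` is FALSE.
#' @export
quantify_labeling <- function(profiles15, profiles14, total_abundance,
                              margin = 0.10, manual_set = NULL) {
  if (inherits(profiles15, "fraction_profile")) profiles15 <- list(profiles15)
  if (inherits(profiles14, "fraction_profile")) profiles14 <- list(profiles14)
  stopifnot(length(profiles15) == length(profiles14),
            length(profiles15) >= 1)
  n_reps <- length(profiles15)
  total_abundance <- rep_len(total_abundance, n_reps)
  gene <- attr(profiles15[[1]], "gene")

  mean15 <- mean_profile(profiles15)
  mean14 <- mean_profile(profiles14)
  hf <- identify_heavy_fractions(mean15, mean14, margin = margin,
                                 manual_set = manual_set)
  labeled <- length(hf) > 0

  if (labeled) {
    ratios <- vapply(profiles15, hf_ratio, numeric(1), hf_set = hf)
    ab <- labeled_abundance(ratios, total_abundance)
    se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
    out <- data.frame(
      gene = gene, n_reps = n_reps,
      hf_fractions = paste(hf, collapse = "-"),
      hf_ratio = mean(ratios), hf_ratio_se = se(ratios),
      total_abundance = mean(total_abundance),
      labeled_abundance = mean(ab), labeled_abundance_se = se(ab),
      peak_bd_15N = peak_bd(mean15), peak_bd_14N = peak_bd(mean14),
      labeled = TRUE)
  } else {
    out <- data.frame(
      gene = gene, n_reps = n_reps, hf_fractions = "",
      hf_ratio = NA_real_, hf_ratio_se = NA_real_,
      total_abundance = mean(total_abundance),
      labeled_abundance = NA_real_, labeled_abundance_se = NA_real_,
      peak_bd_15N = peak_bd(mean15), peak_bd_14N = peak_bd(mean14),
      labeled = FALSE)
  }
  class(out) <- c("labeling_estimate", "data.frame")
  out
}

# replicate-mean profile on the shared grid: each replicate is normalized
# to its own maximum first, so replicates with different absolute yields
# contribute equally to the profile shape
mean_profile <- function(profiles) {
  base <- profiles[[1]]
  norm <- vapply(profiles, normalize_profile, numeric(nrow(base)))
  fraction_profile(
    gene = attr(base, "gene"), treatment = attr(base, "treatment"),
    fractions = data.frame(fraction_index = base$fraction_index,
                           buoyant_density = base$buoyant_density,
                           copies = rowMeans(norm)),
    replicate = "mean", soil = attr(base, "soil"))
}
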