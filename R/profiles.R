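#' Construct a per-fraction gene-abundance profile
#'
#' One profile is one marker gene under one treatment in one replicate: an
#' ordered table of (fraction index, buoyant density, gene copies) across
#' the full gradient. Fraction 1 is the heaviest (collected from the tube
#' bottom), so buoyant density decreases with index.
#'
#' @param gene marker gene label (e.g. "AOA", "AOB", "ComA", "ComB", "16S").
#' @param treatment treatment label (e.g. "CK", "14N-urea", "15N-urea",
#'   "15N-urea+C2H2").
#' @param fractions data.frame with columns `fraction_index`,
#'   `buoyant_density`, `copies`.
#' @param replicate replicate id.
#' @param soil soil label.
#' @return A `fraction_profile`: the fractions data.frame (sorted by index)
#'   with gene/treatment/replicate/soil attached as attributes.
#' @export
fraction_profile <- function(gene, treatment, fractions, replicate = 1L,
                             soil = NA_character_) {
  stopifnot(is.data.frame(fractions),
            all(c("fraction_index", "buoyant_density", "copies")
                %in% names(fractions)))
  fractions <- fractions[order(fractions$fraction_index),
                         c("fraction_index", "buoyant_density", "copies")]
  idx <- fractions$fraction_index
  if (anyDuplicated(idx)) {
    stop("duplicate fraction indices", call. = FALSE)
  }
  if (!identical(as.integer(idx), seq_len(nrow(fractions)))) {
    missing <- setdiff(seq_len(max(idx)), idx)
    stop("fraction indices must be contiguous from 1; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- diff(fractions$buoyant_density)
  if (!(all(d > 0) || all(d < 0))) {
    stop("buoyant density must be strictly monotone across fractions",
         call. = FALSE)
  }
  if (any(fractions$copies < 0)) stop("copies must be >= 0", call. = FALSE)
  rownames(fractions) <- NULL
  structure(fractions,
            gene = gene, treatment = treatment,
            replicate = replicate, soil = soil,
            class = c("fraction_profile", "data.frame"))
}

#' @export
print.fraction_profile <- function(x, ...) {
  cat(sprintf("<fraction_profile> gene=%s treatment=%s replicate=%s soil=%s\n",
              attr(x, "gene"), attr(x, "treatment"),
              attr(x, "replicate"), attr(x, "soil")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Normalize a fraction profile to its maximum
#'
#' Scales per-fraction gene copies to the fraction with the most copies, the
#' convention used to plot SIP profiles from different treatments on a
#' common 0–1 axis: each value is the ratio of that fraction's copy number
#' to the maximum across the gradient.
#'
#' @param profile a [fraction_profile()] (or data.frame with a `copies`
#'   column) with at least one positive fraction.
#' @return Numeric vector of normalized values in \[0, 1\], named by
#'   fraction index; the maximum is exactly 1.
#' @export
normalize_profile <- function(profile) {
  copies <- profile$copies
  m <- max(copies)
  if (m <= 0) {
    stop("no signal: all fractions are zero; cannot normalize", call. = FALSE)
  }
  setNames(copies / m, profile$fraction_index)
}

#' Buoyant density of the profile peak
#'
#' Returns the buoyant density of the fraction with maximal copies. Ties are
#' broken toward the heavier fraction, since isotope labeling is evidenced
#' by mass on the heavy side.
#'
#' @param profile a [fraction_profile()].
#' @return Peak buoyant density, g/mL.
#' @export
peak_bd <- function(profile) {
  profile$buoyant_density[peak_index_pos(profile)]
}

# row position (not index label) of the peak, ties toward higher BD
peak_index_pos <- function(profile) {
  copies <- profile$copies
  m <- max(copies)
  if (m <= 0) stop("no signal: all fractions are zero", call. = FALSE)
  cand <- which(copies == m)
  cand[which.max(profile$buoyant_density[cand])]
}
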