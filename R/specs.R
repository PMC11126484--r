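#' Describe a simulated nitrifier population
#'
#' A taxon specification carries everything the gradient simulator needs to
#' band one population: its total marker-gene abundance, genome GC fraction
#' (which sets the unlabeled banding density), the 15N atom fraction of its
#' DNA (which sets the labeling shift), and the width of its density band.
#'
#' @param name taxon label.
#' @param total_copies marker-gene copies per g dry soil (>= 0).
#' @param gc GC fraction in \[0, 1\].
#' @param atom15n 15N atom fraction in \[0, 1\]; 0 for an unlabeled
#'   (inactive or 14N-grown) population.
#' @param band_sigma standard deviation of the buoyant-density band, g/mL.
#'   Default 0.004, a typical equilibrium band width for genomic DNA.
#' @param gene marker gene assayed (taxa sharing a `gene` are co-amplified
#'   and summed per fraction).
#' @return An object of class `taxon_spec`.
#' @examples
#' taxon_spec("AOB-1", 1e7, gc = 0.5, atom15n = 1)
#' @export
taxon_spec <- function(name, total_copies, gc, atom15n = 0,
                       band_sigma = 0.004, gene = "amoA") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(total_copies) || length(total_copies) != 1L ||
      !is.finite(total_copies) || total_copies < 0) {
    stop("total_copies must be a single non-negative number", call. = FALSE)
  }
  check_fraction(gc, "gc")
  check_fraction(atom15n, "atom15n")
  if (!is.numeric(band_sigma) || band_sigma <= 0) {
    stop("band_sigma must be > 0", call. = FALSE)
  }
  structure(
    list(name = name, total_copies = total_copies, gc = gc,
         atom15n = atom15n, band_sigma = band_sigma, gene = gene),
    class = "taxon_spec"
  )
}

#' Describe the gradient fractionation protocol
#'
#' Defaults mirror a standard CsCl SIP protocol: 16 fractions of 330 uL
#' collected from the bottom of the tube (fraction 1 heaviest), spanning a
#' linear density range wide enough to bracket both native and 15N-labeled
#' DNA. qPCR observation noise is multiplicative log-normal, and fractions
#' reading below the assay detection floor are reported as zero.
#'
#' @param n_fractions number of collected fractions (>= 2), default 16.
#' @param fraction_volume per-fraction volume in uL (metadata only).
#' @param bd_top buoyant density of the lightest fraction boundary, g/mL.
#' @param bd_bottom buoyant density of the heaviest fraction boundary, g/mL;
#'   must exceed `bd_top`.
#' @param qpcr_noise_sigma sd of the log10 multiplicative qPCR noise (>= 0).
#' @param detection_floor copies below which a fraction reads 0.
#' @return An object of class `gradient_protocol`.
#' @export
gradient_protocol <- function(n_fractions = 16, fraction_volume = 330,
                              bd_top = 1.660, bd_bottom = 1.780,
                              qpcr_noise_sigma = 0.1, detection_floor = 10) {
  if (n_fractions < 2) stop("n_fractions must be >= 2", call. = FALSE)
  if (bd_bottom <= bd_top) stop("bd_bottom must exceed bd_top", call. = FALSE)
  if (qpcr_noise_sigma < 0) stop("qpcr_noise_sigma must be >= 0", call. = FALSE)
  if (detection_floor < 0) stop("detection_floor must be >= 0", call. = FALSE)
  structure(
    list(n_fractions = as.integer(n_fractions),
         fraction_volume = fraction_volume,
         bd_top = bd_top, bd_bottom = bd_bottom,
         qpcr_noise_sigma = qpcr_noise_sigma,
         detection_floor = detection_floor),
    class = "gradient_protocol"
  )
}

# fraction windows on a linear BD grid; fraction 1 is the heaviest
# (collected first from the tube bottom)
fraction_grid <- function(protocol) {
  n <- protocol$n_fractions
  w <- (protocol$bd_bottom - protocol$bd_top) / n
  hi <- protocol$bd_bottom - (seq_len(n) - 1) * w
  lo <- hi - w
  data.frame(fraction_index = seq_len(n), bd_lo = lo, bd_hi = hi,
             buoyant_density = (lo + hi) / 2)
}

#' Describe a urea-amended soil microcosm
#'
#' Parameters of the two-pool first-order nitrogen model used by
#' [simulate_microcosm()]: urea hydrolyzes to ammonium, ammonium is oxidized
#' to nitrate, and acetylene suppresses the oxidation step by
#' `inhibition_factor`. Default dosing is four additions of 100 mg N/kg dry
#' soil on days 0, 7, 14 and 21 of a 28-day incubation — split dosing avoids
#' the ammonia spike a single large urea addition would cause.
#'
#' @param nh4_0,no3_0 initial NH4+-N and NO3--N, mg N/kg dry soil.
#' @param urea_doses data.frame with columns `day`, `amount` (mg N/kg).
#' @param hydrolysis_rate first-order urea hydrolysis rate, 1/day.
#' @param nitrification_rate_constant first-order NH4+ oxidation rate, 1/day.
#' @param inhibition_factor fraction of nitrification suppressed, in
#'   \[0, 1\] (1 = complete acetylene inhibition).
#' @param duration incubation length, days.
#' @param dt integration step, days.
#' @return An object of class `microcosm_params`.
#' @export
microcosm_params <- function(nh4_0 = 19.78, no3_0 = 1.95,
                             urea_doses = data.frame(
                               day = c(0, 7, 14, 21),
                               amount = rep(100, 4)),
                             hydrolysis_rate = 0.5,
                             nitrification_rate_constant = 0.008,
                             inhibition_factor = 0,
                             duration = 28, dt = 0.25) {
  if (hydrolysis_rate < 0 || nitrification_rate_constant < 0) {
    stop("rates must be >= 0", call. = FALSE)
  }
  check_fraction(inhibition_factor, "inhibition_factor")
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  stopifnot(is.data.frame(urea_doses),
            all(c("day", "amount") %in% names(urea_doses)))
  structure(
    list(nh4_0 = nh4_0, no3_0 = no3_0, urea_doses = urea_doses,
         hydrolysis_rate = hydrolysis_rate,
         nitrification_rate_constant = nitrification_rate_constant,
         inhibition_factor = inhibition_factor,
         duration = duration, dt = dt),
    class = "microcosm_params"
  )
}
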