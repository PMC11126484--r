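#' Read a per-fraction qPCR table into fraction profiles
#'
#' Expects a TSV with header columns `gene`, `treatment`, `replicate`,
#' `fraction_index`, `copies_per_g`, and either `buoyant_density_g_ml` or
#' `refractive_index` (converted via [ri_to_bd()]); an optional `soil`
#' column is carried through. Rows are grouped into one
#' [fraction_profile()] per (soil, gene, treatment, replicate), and each
#' profile is validated: unique contiguous fraction indices starting at 1,
#' strictly monotone buoyant density, non-negative copies.
#'
#' @param path TSV file path.
#' @param n_fractions if given, every profile must have exactly this many
#'   fractions (e.g. 16 for the standard protocol).
#' @return Named list of `fraction_profile` objects.
#' @export
read_fraction_table <- function(path, n_fractions = NULL) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("gene", "treatment", "replicate", "fraction_index", "copies_per_g")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("fraction table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("buoyant_density_g_ml" %in% names(df)) {
    df$bd <- df$buoyant_density_g_ml
  } else if ("refractive_index" %in% names(df)) {
    df$bd <- ri_to_bd(df$refractive_index)
  } else {
    stop("fraction table needs buoyant_density_g_ml or refractive_index",
         call. = FALSE)
  }
  if (!"soil" %in% names(df)) df$soil <- NA_character_

  key <- paste(df$soil, df$gene, df$treatment, df$replicate, sep = "\r")
  dup <- duplicated(data.frame(key, df$fraction_index))
  if (any(dup)) {
    stop("duplicate (gene, treatment, replicate, fraction) row(s) at line(s): ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  profiles <- lapply(split(df, key), function(d) {
    p <- fraction_profile(
      gene = d$gene[1], treatment = d$treatment[1],
      fractions = data.frame(fraction_index = d$fraction_index,
                             buoyant_density = d$bd,
                             copies = d$copies_per_g),
      replicate = d$replicate[1], soil = d$soil[1])
    if (!is.null(n_fractions) && nrow(p) != n_fractions) {
      stop(sprintf("profile %s/%s/%s has %d fractions, expected %d",
                   d$gene[1], d$treatment[1], d$replicate[1],
                   nrow(p), n_fractions), call. = FALSE)
    }
    p
  })
  profiles
}

#' Write fraction profiles (or a gradient dataset) as a TSV
#'
#' @param x a `gradient_dataset`, a single [fraction_profile()], or a list
#'   of profiles.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fraction_table <- function(x, path) {
  if (inherits(x, "gradient_dataset")) x <- x$profiles
  if (inherits(x, "fraction_profile")) x <- list(x)
  rows <- lapply(x, function(p) {
    data.frame(soil = attr(p, "soil"), gene = attr(p, "gene"),
               treatment = attr(p, "treatment"),
               replicate = attr(p, "replicate"),
               fraction_index = p$fraction_index,
               buoyant_density_g_ml = p$buoyant_density,
               copies_per_g = p$copies)
  })
  write_tsv(do.call(rbind, c(rows, make.row.names = FALSE)), path)
}

#' Read a microcosm chemistry time series TSV
#'
#' Expects columns `treatment`, `replicate`, `day`, `nh4_mg_kg`,
#' `no3_mg_kg` (optional `soil`); days must be non-negative and
#' concentrations non-negative.
#'
#' @param path TSV file path.
#' @return data.frame sorted by (treatment, replicate, day).
#' @export
read_chem_table <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("treatment", "replicate", "day", "nh4_mg_kg", "no3_mg_kg")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("chemistry table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$day < 0)) stop("days must be >= 0", call. = FALSE)
  if (any(df$nh4_mg_kg < 0 | df$no3_mg_kg < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  df[order(df$treatment, df$replicate, df$day), , drop = FALSE]
}

#' Read Zotu counts, sample metadata and taxonomy TSVs
#'
#' The counts TSV has Zotus as rows (first column `zotu`) and samples as
#' remaining columns; metadata and taxonomy TSVs are keyed by `sample` and
#' `zotu` respectively. Validation is delegated to [zotu_table()].
#'
#' @param counts_path,samples_path,taxonomy_path TSV file paths.
#' @return A [zotu_table()].
#' @export
read_zotu_table <- function(counts_path, samples_path, taxonomy_path) {
  cts <- read.delim(counts_path, sep = "\t", check.names = FALSE)
  if (names(cts)[1] != "zotu") {
    stop("counts TSV must have 'zotu' as its first column", call. = FALSE)
  }
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$zotu
  zotu_table(m,
             samples = read.delim(samples_path, sep = "\t"),
             taxonomy = read.delim(taxonomy_path, sep = "\t"))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

log_stage <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

# allowed keys per config block; unknown keys are rejected loudly
.CONFIG_SCHEMA <- list(
  "." = c("seed", "out_dir", "simulate", "quantify", "rates", "community"),
  "simulate" = c("gradient", "microcosm"),
  "simulate.gradient" = c("soil", "genes", "n_replicates", "protocol"),
  "simulate.microcosm" = c("soil", "nh4_0", "no3_0", "urea_doses",
                           "hydrolysis_rate", "nitrification_rate_constant",
                           "inhibition_factor", "duration", "dt",
                           "noise_sd", "sample_days", "n_replicates",
                           "treatments"),
  "quantify" = c("fractions", "totals", "margin", "hf_overrides"),
  "rates" = c("chem", "inhibited_treatment", "uninhibited_treatment"),
  "community" = c("counts", "samples", "taxonomy", "fasta", "hf_group",
                  "ref_group", "min_abund", "fold", "top_n", "level")
)

check_keys <- function(block, where) {
  allowed <- .CONFIG_SCHEMA[[where]]
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop("unknown config key(s) in '", where, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(block)
}

#' Read and validate a pipeline run configuration
#'
#' YAML configuration mirroring the pipeline stages (`simulate`,
#' `quantify`, `rates`, `community`) plus `seed` and `out_dir`. Unknown
#' keys anywhere in the file are rejected with an error listing them, and
#' referenced input paths must exist at load time.
#'
#' @param path YAML file path.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, ".")
  if (is.null(cfg$seed) || cfg$seed != as.integer(cfg$seed)) {
    stop("config must set an integer seed", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$out_dir)) stop("config must set out_dir", call. = FALSE)
  if (!is.null(cfg$simulate)) {
    check_keys(cfg$simulate, "simulate")
    if (!is.null(cfg$simulate$gradient)) {
      check_keys(cfg$simulate$gradient, "simulate.gradient")
    }
    if (!is.null(cfg$simulate$microcosm)) {
      check_keys(cfg$simulate$microcosm, "simulate.microcosm")
    }
  }
  for (block in c("quantify", "rates", "community")) {
    if (!is.null(cfg[[block]])) check_keys(cfg[[block]], block)
  }
  paths <- as.character(c(cfg$quantify$fractions, cfg$rates$chem,
                          cfg$community$counts, cfg$community$samples,
                          cfg$community$taxonomy, cfg$community$fasta))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("config references missing file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the SIP analysis pipeline from a configuration
#'
#' Executes the configured stages in order — simulate (optional) →
#' quantify → rates → community — writing each stage's TSV outputs and a
#' machine-readable `manifest.json` (inputs, seed, thresholds, package
#' version, stages run or skipped) to `out_dir`. Runs are deterministic for
#' a fixed seed: repeating a run produces byte-identical outputs. Stages
#' whose config block is absent are skipped and noted in the manifest.
#'
#' @param config a [read_run_config()] result, or a path to a YAML config.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(packageVersion("nsip")),
                   seed = config$seed, stages = list(), thresholds = list(),
                   outputs = character(0))
  sim_gradient <- NULL
  sim_totals <- NULL
  sim_chem_path <- NULL

  # --- simulate -------------------------------------------------------
  if (!is.null(config$simulate)) {
    if (!is.null(config$simulate$gradient)) {
      g <- config$simulate$gradient
      log_stage("simulate: gradient (%d gene(s))", length(g$genes))
      protocol <- do.call(gradient_protocol, as.list(g$protocol))
      taxa <- mapply(function(nm, spec) {
        do.call(taxon_spec, c(list(name = nm, gene = nm),
                              coerce_numeric(spec)))
      }, names(g$genes), g$genes, SIMPLIFY = FALSE)
      n_reps <- if (is.null(g$n_replicates)) 3L else as.integer(g$n_replicates)
      reps <- lapply(seq_len(n_reps), function(r) {
        sim <- simulate_sip_experiment(
          taxa, protocol, seed = config$seed + r,
          soil = if (is.null(g$soil)) NA_character_ else g$soil)
        lapply(sim, function(ds) {
          ds$profiles <- lapply(ds$profiles, function(p) {
            attr(p, "replicate") <- r
            p
          })
          ds
        })
      })
      profiles <- unlist(lapply(reps, function(sim) {
        c(sim$label15N$profiles, sim$label14N$profiles)
      }), recursive = FALSE)
      path <- file.path(out_dir, "fractions.tsv")
      write_fraction_table(profiles, path)
      sim_gradient <- profiles
      sim_totals <- vapply(taxa, `[[`, numeric(1), "total_copies")
      names(sim_totals) <- vapply(taxa, `[[`, character(1), "gene")
      manifest$stages$simulate_gradient <- "run"
      manifest$outputs <- c(manifest$outputs, path)
    }
    if (!is.null(config$simulate$microcosm)) {
      m <- config$simulate$microcosm
      log_stage("simulate: microcosm")
      fixed <- coerce_numeric(
        m[setdiff(names(m), c("soil", "noise_sd", "sample_days",
                              "n_replicates", "treatments"))])
      if (!is.null(fixed$urea_doses)) {
        fixed$urea_doses <- do.call(rbind.data.frame, fixed$urea_doses)
      }
      n_reps <- if (is.null(m$n_replicates)) 3L else as.integer(m$n_replicates)
      treatments <- if (is.null(m$treatments)) "15N-urea" else m$treatments
      noise_sd <- if (is.null(m$noise_sd)) 0 else m$noise_sd
      series <- list()
      for (tr in treatments) {
        p <- do.call(microcosm_params, fixed)
        if (grepl("C2H2", tr)) p$inhibition_factor <- 1
        for (r in seq_len(n_reps)) {
          series[[paste(tr, r)]] <- simulate_microcosm(
            p, seed = config$seed + 1000L + 10L * match(tr, treatments) + r,
            sample_days = m$sample_days, noise_sd = noise_sd,
            treatment = tr, replicate = r,
            soil = if (is.null(m$soil)) NA_character_ else m$soil)
        }
      }
      chem <- do.call(rbind, c(lapply(series, as.data.frame),
                               make.row.names = FALSE))
      sim_chem_path <- file.path(out_dir, "chemistry.tsv")
      write_tsv(chem, sim_chem_path)
      manifest$stages$simulate_microcosm <- "run"
      manifest$outputs <- c(manifest$outputs, sim_chem_path)
    }
  }

  # --- quantify -------------------------------------------------------
  if (!is.null(config$quantify) || !is.null(sim_gradient)) {
    q <- if (is.null(config$quantify)) list() else config$quantify
    margin <- if (is.null(q$margin)) 0.10 else q$margin
    profiles <- if (!is.null(q$fractions)) {
      read_fraction_table(q$fractions)
    } else if (!is.null(sim_gradient)) {
      sim_gradient
    } else {
      stop("quantify stage: no fraction table configured or simulated",
           call. = FALSE)
    }
    totals <- if (!is.null(q$totals)) {
      unlist(coerce_numeric(q$totals))
    } else {
      sim_totals
    }
    if (is.null(totals)) {
      stop("quantify stage: no total abundances configured", call. = FALSE)
    }
    log_stage("quantify: %d profile group(s), margin %.2f",
              length(profiles), margin)
    genes <- unique(vapply(profiles, attr, character(1), "gene"))
    est <- lapply(genes, function(g) {
      is_g <- vapply(profiles, function(p) attr(p, "gene") == g, logical(1))
      tr <- vapply(profiles, function(p) attr(p, "treatment"), character(1))
      p15 <- profiles[is_g & grepl("^15N", tr)]
      p14 <- profiles[is_g & grepl("^14N", tr)]
      if (!length(p15) || !length(p14)) return(NULL)
      manual <- parse_hf_override(q$hf_overrides[[g]])
      quantify_labeling(p15, p14, total_abundance = totals[[g]],
                        margin = margin, manual_set = manual)
    })
    est <- do.call(rbind, c(est[!vapply(est, is.null, logical(1))],
                            make.row.names = FALSE))
    path <- file.path(out_dir, "labeling_estimates.tsv")
    write_tsv(est, path)
    manifest$stages$quantify <- "run"
    manifest$thresholds$margin <- margin
    manifest$outputs <- c(manifest$outputs, path)
  } else {
    manifest$stages$quantify <- "skipped"
  }

  # --- rates ----------------------------------------------------------
  chem_path <- if (!is.null(config$rates$chem)) config$rates$chem else sim_chem_path
  if (!is.null(chem_path)) {
    log_stage("rates: %s", chem_path)
    chem <- read_chem_table(chem_path)
    key <- interaction(chem$treatment, chem$replicate, drop = TRUE)
    rates <- do.call(rbind, c(lapply(split(chem, key), function(d) {
      d <- d[order(d$day), ]
      data.frame(treatment = d$treatment[1], replicate = d$replicate[1],
                 days = d$day[nrow(d)] - d$day[1],
                 delta_no3 = d$no3_mg_kg[nrow(d)] - d$no3_mg_kg[1],
                 delta_nh4 = d$nh4_mg_kg[nrow(d)] - d$nh4_mg_kg[1],
                 net_nitrification_rate = net_nitrification_rate(
                   d$no3_mg_kg[1], d$no3_mg_kg[nrow(d)],
                   d$day[nrow(d)] - d$day[1]))
    }), make.row.names = FALSE))
    r <- config$rates
    if (!is.null(r$inhibited_treatment) && !is.null(r$uninhibited_treatment)) {
      di <- mean(rates$delta_no3[rates$treatment == r$inhibited_treatment])
      du <- mean(rates$delta_no3[rates$treatment == r$uninhibited_treatment])
      rates$inhibition_percent <- NA_real_
      rates$inhibition_percent[rates$treatment == r$inhibited_treatment] <-
        inhibition_percent(di, du)
    }
    path <- file.path(out_dir, "rates.tsv")
    write_tsv(rates, path)
    manifest$stages$rates <- "run"
    manifest$outputs <- c(manifest$outputs, path)
  } else {
    log_stage("rates: no chemistry table; stage skipped")
    manifest$stages$rates <- "skipped"
  }

  # --- community ------------------------------------------------------
  if (!is.null(config$community)) {
    cm <- config$community
    log_stage("community: %s", cm$counts)
    tab <- read_zotu_table(cm$counts, cm$samples, cm$taxonomy)
    if (!is.null(cm$fasta)) check_zotu_fasta(cm$fasta, tab)
    level <- if (is.null(cm$level)) "zotu" else cm$level
    top_n <- if (is.null(cm$top_n)) 10 else cm$top_n
    min_abund <- if (is.null(cm$min_abund)) 0.01 else cm$min_abund
    fold <- if (is.null(cm$fold)) 2 else cm$fold
    comp <- clade_composition(tab, cm$hf_group)
    top <- top_n_taxa(tab, cm$hf_group, n = top_n, level = level)
    act <- active_taxa(tab, cm$hf_group, cm$ref_group,
                       min_abund = min_abund, fold = fold, level = level)
    paths <- file.path(out_dir, c("clade_composition.tsv", "top_taxa.tsv",
                                  "active_taxa.tsv"))
    write_tsv(comp, paths[1]); write_tsv(top, paths[2]); write_tsv(act, paths[3])
    manifest$stages$community <- "run"
    manifest$thresholds$min_abund <- min_abund
    manifest$thresholds$fold <- fold
    manifest$outputs <- c(manifest$outputs, paths)
  } else {
    manifest$stages$community <- "skipped"
  }

  manifest$outputs <- basename(manifest$outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("pipeline complete: %s", out_dir)
  invisible(manifest)
}

# YAML scalars like "2.41e8" arrive as strings; coerce the numeric-looking
# ones so config values behave like numbers
coerce_numeric <- function(x) {
  lapply(x, function(v) {
    if (is.character(v) && length(v) == 1) {
      nv <- suppressWarnings(as.numeric(v))
      if (!is.na(nv)) return(nv)
    }
    v
  })
}

# "7-9" or c(7, 8, 9) -> integer vector; NULL passes through
parse_hf_override <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1 && grepl("-", x)) {
    parts <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
    return(seq(parts[1], parts[2]))
  }
  as.integer(x)
}
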