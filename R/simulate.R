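#' Pyrosequencing-style error model
#'
#' Parameters of the simulated sequencing error process. Substitutions occur
#' per base; homopolymer length errors (the characteristic pyrosequencing
#' failure mode) occur per homopolymer run of length >= 3 with probability
#' `homopolymer_base_rate * (run_length - 1)`, over- and undercall
#' equiprobable. Runs near the 5' end of the targeted exon are hit
#' `reverse_bias` times more often on reverse-orientation reads, emulating
#' the direction asymmetry that makes forward reads the safe evidence for
#' positions such as the 5-base C homopolymer at the start of C*07 exon 4.
#' DRB exon 2 additionally receives crossover chimeras (5' half from DRB1,
#' 3' half from DRB3/4/5) and pseudogene reads.
#'
#' The quantitative defaults are tunable package choices, not published
#' instrument constants.
#'
#' @param substitution_rate Per-base substitution probability.
#' @param homopolymer_base_rate Per-run base probability (scaled by run
#'   length - 1).
#' @param reverse_bias Multiplier for exon-start homopolymer errors on
#'   reverse reads.
#' @param chimera_rate Per-read probability of a DRB1 x DRB3/4/5 crossover
#'   chimera on DRB exon 2.
#' @param pseudogene_fraction Fraction of DRB exon 2 reads drawn from the
#'   pseudo-locus.
#' @return A list of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.001,
                        homopolymer_base_rate = 0.005,
                        reverse_bias = 3,
                        chimera_rate = 0.05,
                        pseudogene_fraction = 0.10) {
  probs <- c(substitution_rate, homopolymer_base_rate, chimera_rate,
             pseudogene_fraction)
  if (any(probs < 0 | probs > 1)) abort("error-model probabilities must be in [0,1]")
  structure(
    list(substitution_rate = substitution_rate,
         homopolymer_base_rate = homopolymer_base_rate,
         reverse_bias = reverse_bias,
         chimera_rate = chimera_rate,
         pseudogene_fraction = pseudogene_fraction),
    class = "error_model"
  )
}

#' Zero-error model (exact reads)
#' @return An `error_model` with all rates 0.
#' @export
perfect_reads <- function() {
  error_model(0, 0, 1, 0, 0)
}

#' Simulate diploid genotypes
#'
#' Draws one ordered allele pair per sample and locus from the database;
#' with probability `homozygote_rate` the pair is homozygous (the validation
#' panel design point is 10.3% homozygous genotypes).
#'
#' @param db An `hla_allele_db`.
#' @param n_samples Number of samples.
#' @param homozygote_rate Probability that a sample/locus genotype is
#'   homozygous.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param loci Loci to genotype (default: all typing loci in the database).
#' @param panel Optional `hla_panel`; when given, samples are assigned the
#'   panel's MIDs in order and `n_samples` must not exceed the MID count.
#' @return A tibble (`sample_id`, `mid_id`, `locus`, `allele1`, `allele2`).
#' @export
simulate_genotypes <- function(db, n_samples, homozygote_rate = 0.103, seed,
                               loci = typing_loci(db), panel = NULL) {
  stopifnot(inherits(db, "hla_allele_db"), n_samples >= 1)
  for (lc in loci) {
    if (length(locus_alleles(db, lc)) < 2) {
      abort(sprintf("locus %s has fewer than 2 alleles", lc))
    }
  }
  mid_ids <- rep(NA_character_, n_samples)
  if (!is.null(panel)) {
    if (n_samples > nrow(panel$mids)) {
      abort(sprintf("n_samples (%d) exceeds available MIDs (%d)",
                    n_samples, nrow(panel$mids)))
    }
    mid_ids <- panel$mids$mid_id[seq_len(n_samples)]
  }
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      sample_id = sprintf("S%02d", seq_len(n_samples)),
      locus = loci
    )
    grid$mid_id <- mid_ids[match(grid$sample_id,
                                 sprintf("S%02d", seq_len(n_samples)))]
    draws <- purrr::map(grid$locus, function(lc) {
      alleles <- locus_alleles(db, lc)
      a1 <- sample(alleles, 1)
      if (stats::runif(1) < homozygote_rate) {
        c(a1, a1)
      } else {
        c(a1, sample(setdiff(alleles, a1), 1))
      }
    })
    grid |>
      dplyr::mutate(
        allele1 = vapply(draws, `[`, character(1), 1),
        allele2 = vapply(draws, `[`, character(1), 2)
      ) |>
      dplyr::select("sample_id", "mid_id", "locus", "allele1", "allele2")
  })
}

# Homopolymer runs (length >= 3) of a sequence: tibble(pos, len, base).
homopolymer_runs <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  pos <- cumsum(c(1L, utils::head(r$lengths, -1)))
  keep <- r$lengths >= 3
  tibble(pos = pos[keep], len = r$lengths[keep], base = r$values[keep])
}

# Apply homopolymer +-1 errors (run indices `hits`, sign per hit) and then
# `n_sub` random substitutions to a sequence. Returns the mutated string.
mutate_sequence <- function(seq, runs, hits, signs, n_sub) {
  if (length(hits) > 0) {
    ord <- order(runs$pos[hits], decreasing = TRUE)
    for (k in ord) {
      i <- hits[k]
      p <- runs$pos[i]
      if (signs[k] > 0) {
        seq <- paste0(substr_safe(seq, 1, p), runs$base[i],
                      substr_safe(seq, p + 1L, nchar(seq)))
      } else {
        seq <- paste0(substr_safe(seq, 1, p - 1L),
                      substr_safe(seq, p + 1L, nchar(seq)))
      }
    }
  }
  if (n_sub > 0) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    pos <- sample.int(length(ch), min(n_sub, length(ch)))
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    seq <- paste(ch, collapse = "")
  }
  seq
}

#' Simulate an amplicon sequencing run
#'
#' Emits fusion-primer reads for every sample and panel amplicon:
#' each read is `MID || primer || template-with-errors`, in forward or
#' reverse orientation (reverse reads reverse-complemented, starting with
#' the reverse primer). Primer footprints carry the reference primer
#' sequence (the primer overwrites the template there, which is exactly why
#' variants under a primer are invisible). Per-amplicon depth is negative
#' binomial with mean `mean_depth * pooling_factor`, short-pool amplicons
#' boosted by `short_boost` to mimic their higher emulsion-PCR efficiency.
#' DRB exon 2 reads include pseudogene and crossover-chimera reads per the
#' error model.
#'
#' @param truth Genotype tibble from [simulate_genotypes()].
#' @param db An `hla_allele_db` (fully annotated; alleles lacking a feature
#'   required by an amplicon are skipped with a warning).
#' @param panel An `hla_panel`.
#' @param mean_depth Mean reads per factor-1 amplicon.
#' @param model An [error_model()].
#' @param seed Integer seed; same seed gives byte-identical output.
#' @param short_boost Depth multiplier for short-pool amplicons.
#' @param nb_size Negative-binomial size (dispersion) parameter.
#' @param run_id Run identifier recorded in read names and the association.
#' @return A list: `reads` (tibble `read_id`, `sequence`, plus truth columns
#'   `sample_id`, `amplicon`, `allele`, `allele2` (chimera partner),
#'   `direction`, `class`, `n_sub`, `n_hp`), `association` (tibble
#'   `sample_id`, `mid_id`, `mid`, `run_id`), and `run_id`.
#' @export
simulate_reads <- function(truth, db, panel, mean_depth = 182,
                           model = error_model(), seed,
                           short_boost = 1.4, nb_size = 10,
                           run_id = sprintf("RUN%05d", seed %% 100000L)) {
  if (nrow(truth) == 0) abort("empty truth set")
  samples <- unique(truth$sample_id)
  if (length(samples) > nrow(panel$mids)) {
    abort("more samples than available MIDs")
  }
  mid_map <- truth |>
    dplyr::distinct(.data$sample_id) |>
    dplyr::mutate(idx = dplyr::row_number())
  assoc0 <- truth |> dplyr::distinct(.data$sample_id, .data$mid_id)
  if (all(!is.na(assoc0$mid_id))) {
    association <- assoc0 |>
      dplyr::left_join(panel$mids, by = "mid_id") |>
      dplyr::rename(mid = "sequence")
  } else {
    association <- mid_map |>
      dplyr::mutate(mid_id = panel$mids$mid_id[.data$idx],
                    mid = panel$mids$sequence[.data$idx]) |>
      dplyr::select("sample_id", "mid_id", "mid")
  }
  association$run_id <- run_id

  lay <- amplicon_layout(panel, db)
  # per (amplicon, allele): product, homopolymer runs, exon-start window
  prod_tbl <- purrr::map_dfr(seq_len(nrow(lay)), function(i) {
    row <- lay[i, ]
    loci <- intersect(amplicon_target_loci(row$locus, with_pseudo = TRUE),
                      db$loci)
    purrr::map_dfr(loci, function(lc) {
      purrr::map_dfr(locus_alleles(db, lc), function(a) {
        needed <- needed_span_features(db, row)
        af <- allele_feats(db, a)
        if (!all(needed %in% af$feats$feature)) {
          warn(sprintf("allele %s lacks features for amplicon %s; skipped",
                       a, row$amplicon))
          return(tibble())
        }
        p <- amplicon_product(db, a, row)$product
        tibble(amplicon = row$amplicon, locus = lc, allele = a, product = p)
      })
    })
  })
  prod_tbl$runs <- lapply(prod_tbl$product, homopolymer_runs)
  lay_idx <- match(prod_tbl$amplicon, lay$amplicon)
  # exon 5' start in product coordinates (window where reverse reads see
  # extra homopolymer trouble)
  prod_tbl$exon_start_prod <- nchar(lay$fwd_primer[lay_idx]) +
    (lay$xs[lay_idx] - lay$fwd_end[lay_idx] - 1L) + 1L

  withr::with_seed(seed, {
    reads_spec <- purrr::map_dfr(seq_len(nrow(lay)), function(i) {
      row <- lay[i, ]
      loci <- intersect(amplicon_target_loci(row$locus), unique(truth$locus))
      if (length(loci) == 0) return(tibble())
      purrr::map_dfr(samples, function(sm) {
        gt <- truth[truth$sample_id == sm & truth$locus %in% loci, ]
        if (nrow(gt) == 0) return(tibble())
        templates <- c(rbind(gt$allele1, gt$allele2))
        templates <- templates[paste0(row$amplicon, ":", templates) %in%
                                 paste0(prod_tbl$amplicon, ":", prod_tbl$allele)]
        if (length(templates) == 0) return(tibble())
        mu <- mean_depth * row$pooling_factor *
          if (row$pool == "short") short_boost else 1
        n <- stats::rnbinom(1, mu = mu, size = nb_size)
        if (n == 0) return(tibble())
        is_drb2 <- row$locus == "DRB" && row$exon == 2
        cls <- rep("normal", n)
        if (is_drb2) {
          u <- stats::runif(n)
          pseudo_ok <- "DRBP" %in% db$loci
          drb1 <- templates[startsWith(templates, "DRB1")]
          other <- templates[!startsWith(templates, "DRB1")]
          chim_ok <- length(drb1) > 0 && length(other) > 0
          cls[pseudo_ok & u < model$pseudogene_fraction] <- "pseudogene"
          cls[chim_ok & u >= model$pseudogene_fraction &
                u < model$pseudogene_fraction + model$chimera_rate] <- "chimera"
        }
        tibble(
          sample_id = sm, amplicon = row$amplicon,
          allele = sample(templates, n, replace = TRUE),
          allele2 = NA_character_,
          direction = sample(c("fwd", "rev"), n, replace = TRUE),
          class = cls
        )
      })
    })
    if (nrow(reads_spec) == 0) abort("no reads to simulate")

    # resolve chimera/pseudogene templates
    is_p <- reads_spec$class == "pseudogene"
    if (any(is_p)) {
      pseudo_alleles <- locus_alleles(db, "DRBP")
      reads_spec$allele[is_p] <- sample(pseudo_alleles, sum(is_p), replace = TRUE)
    }
    is_c <- reads_spec$class == "chimera"
    if (any(is_c)) {
      for (k in which(is_c)) {
        sm <- reads_spec$sample_id[k]
        gt <- truth[truth$sample_id == sm, ]
        drb1 <- unique(c(gt$allele1, gt$allele2))
        d1 <- sample(drb1[startsWith(drb1, "DRB1")], 1)
        d345 <- drb1[startsWith(drb1, "DRB3") | startsWith(drb1, "DRB4") |
                       startsWith(drb1, "DRB5")]
        reads_spec$allele[k] <- d1
        reads_spec$allele2[k] <- sample(d345, 1)
      }
    }

    key <- paste0(reads_spec$amplicon, ":", reads_spec$allele)
    pkey <- paste0(prod_tbl$amplicon, ":", prod_tbl$allele)
    pidx <- match(key, pkey)
    products <- prod_tbl$product[pidx]
    # chimeras: splice the two products at a uniform crossover point in the
    # middle of the covered exon
    if (any(is_c)) {
      for (k in which(is_c)) {
        p2 <- prod_tbl$product[match(paste0(reads_spec$amplicon[k], ":",
                                            reads_spec$allele2[k]), pkey)]
        l1 <- nchar(products[k])
        cross <- prod_tbl$exon_start_prod[pidx[k]] +
          sample(110:140, 1)
        cross <- min(cross, l1 - 1L, nchar(p2) - 1L)
        products[k] <- paste0(substr(products[k], 1, cross),
                              substr(p2, cross + 1L, nchar(p2)))
      }
    }

    mids <- association$mid[match(reads_spec$sample_id, association$sample_id)]
    lens <- nchar(products) + 10L
    n_sub <- stats::rbinom(nrow(reads_spec), lens, model$substitution_rate)
    # homopolymer events per read (skipped for chimeric products whose run
    # table no longer applies)
    n_hp <- integer(nrow(reads_spec))
    hp_data <- vector("list", nrow(reads_spec))
    for (k in seq_len(nrow(reads_spec))) {
      if (is_c[k]) next
      runs <- prod_tbl$runs[[pidx[k]]]
      if (nrow(runs) == 0) next
      p <- model$homopolymer_base_rate * (runs$len - 1)
      if (reads_spec$direction[k] == "rev") {
        xs <- prod_tbl$exon_start_prod[pidx[k]]
        near <- runs$pos <= xs + 11L & (runs$pos + runs$len - 1L) >= xs - 1L
        p[near] <- pmin(1, p[near] * model$reverse_bias)
      }
      hit <- which(stats::runif(nrow(runs)) < p)
      if (length(hit) > 0) {
        hp_data[[k]] <- list(hits = hit,
                             signs = sample(c(-1L, 1L), length(hit),
                                            replace = TRUE))
        n_hp[k] <- length(hit)
      }
    }
    sequences <- character(nrow(reads_spec))
    for (k in seq_len(nrow(reads_spec))) {
      p <- products[k]
      if (n_hp[k] > 0 || n_sub[k] > 0) {
        hd <- hp_data[[k]]
        p <- mutate_sequence(p, prod_tbl$runs[[pidx[k]]],
                             hd$hits %||% integer(0), hd$signs %||% integer(0),
                             0L)
        if (reads_spec$direction[k] == "rev") p <- revcomp(p)
        full <- paste0(mids[k], p)
        sequences[k] <- mutate_sequence(full, tibble(), integer(0), integer(0),
                                        n_sub[k])
      } else {
        if (reads_spec$direction[k] == "rev") p <- revcomp(p)
        sequences[k] <- paste0(mids[k], p)
      }
    }
    reads <- reads_spec |>
      dplyr::mutate(
        read_id = sprintf("%s_R%06d", run_id, dplyr::row_number()),
        sequence = sequences, n_sub = n_sub, n_hp = n_hp
      ) |>
      dplyr::select("read_id", "sequence", "sample_id", "amplicon", "allele",
                    "allele2", "direction", "class", "n_sub", "n_hp")
    list(reads = reads, association = association, run_id = run_id)
  })
}

#' Simulate a fluorometric quantification plate
#'
#' An 8-point standard series over 0-100 ng/ul plus per-amplicon signals,
#' all with Gaussian signal noise.
#'
#' @param panel An `hla_panel`.
#' @param true_concs Named vector of true concentrations (ng/ul) per
#'   amplicon; defaults to values drawn uniformly in 20-60 ng/ul.
#' @param noise_sd Signal noise standard deviation (signal units).
#' @param seed Integer seed.
#' @param slope,intercept True signal response.
#' @return A list: `standards` (tibble `conc`, `signal`) and `quants`
#'   (tibble `amplicon`, `signal`, `true_conc`).
#' @export
simulate_quant_plate <- function(panel, true_concs = NULL, noise_sd = 2, seed,
                                 slope = 50, intercept = 2) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  withr::with_seed(seed, {
    amp <- panel$amplicons$amplicon
    if (is.null(true_concs)) {
      true_concs <- stats::setNames(stats::runif(length(amp), 20, 60), amp)
    }
    conc <- seq(0, 100, length.out = 8)
    standards <- tibble(
      conc = conc,
      signal = intercept + slope * conc + stats::rnorm(8, 0, noise_sd)
    )
    quants <- tibble(
      amplicon = amp,
      true_conc = unname(true_concs[amp]),
      signal = intercept + slope * true_concs[amp] +
        stats::rnorm(length(amp), 0, noise_sd)
    )
    list(standards = standards, quants = quants)
  })
}

#' Write simulated reads as FASTA
#'
#' @param reads Read tibble (`read_id`, `sequence`).
#' @param path Output path (conventionally `.fna`).
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a FASTA read set
#'
#' @param path FASTA path.
#' @return A tibble (`read_id`, `sequence`).
#' @export
read_reads_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  x <- Biostrings::readDNAStringSet(path)
  tibble(read_id = names(x), sequence = unname(as.character(x)))
}

#' Write a simulation truth file
#'
#' @param truth Genotype tibble from [simulate_genotypes()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
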