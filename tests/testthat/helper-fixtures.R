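# Shared fixtures, memoised so the suite builds them once.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_db <- function() memo("db", mock_allele_db())
test_panel <- function() memo("panel", mock_panel())
test_layout <- function() memo("layout", amplicon_layout(test_panel(), test_db()))
test_targets <- function(mode = "exon_plus_flank") {
  memo(paste0("targets_", mode),
       build_target_table(test_db(), test_panel(), mode, layout = test_layout()))
}

# A small shared zero-error class I run (3 samples, loci A/B/C).
tiny_clean_run <- function() {
  memo("tiny_clean", {
    db <- test_db(); panel <- test_panel()
    truth <- simulate_genotypes(db, 3, homozygote_rate = 0.2, seed = 11,
                                loci = c("A", "B", "C"), panel = panel)
    sim <- simulate_reads(truth, db, panel, mean_depth = 40,
                          model = perfect_reads(), seed = 12)
    demux <- demultiplex(sim$reads[c("read_id", "sequence")], panel,
                         sim$association, db, layout = test_layout())
    trimmed <- trim_reads(demux, panel, db, mode = "exon_plus_flank",
                          layout = test_layout())
    list(truth = truth, sim = sim, demux = demux, trimmed = trimmed)
  })
}

# Reads for a single hand-picked genotype, zero error.
reads_for_genotype <- function(locus, a1, a2, depth = 60, seed = 33,
                               model = perfect_reads()) {
  db <- test_db(); panel <- test_panel()
  truth <- tibble::tibble(sample_id = "S01", mid_id = NA_character_,
                          locus = locus, allele1 = a1, allele2 = a2)
  sim <- simulate_reads(truth, db, panel, mean_depth = depth, model = model,
                        seed = seed)
  demux <- demultiplex(sim$reads[c("read_id", "sequence")], panel,
                       sim$association, db, layout = test_layout())
  trim_reads(demux, panel, db, mode = "exon_plus_flank", layout = test_layout())
}

# Independent dynamic-programming oracle for the fitting-alignment mismatch
# count: query consumed globally, reference end gaps free, unit costs for
# substitutions and gap bases. Kept brute-force and separate from the
# implementation under test.
dp_fit_distance <- function(query, reference) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  r <- strsplit(reference, "", fixed = TRUE)[[1]]
  n <- length(q); m <- length(r)
  prev <- rep(0, m + 1)            # D[0, j] = 0: free leading reference
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i                    # D[i, 0] = i: query gap bases
    for (j in seq_len(m)) {
      cur[j + 1] <- min(
        prev[j] + (q[i] != r[j]),  # diagonal: match/substitution
        prev[j + 1] + 1,           # gap in reference row (consume query)
        cur[j] + 1                 # gap in query row (consume reference)
      )
    }
    prev <- cur
  }
  min(prev)                        # free trailing reference
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
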