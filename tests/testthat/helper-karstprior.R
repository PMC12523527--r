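# shared fixtures and independent oracles

# deterministic toy occurrence table: 6 caves x 10 species with known counts
toy_occurrences <- function() {
  rows <- list(
    # cave, species, troglobiont
    c("C1", "s1", FALSE), c("C1", "s2", FALSE), c("C1", "t1", TRUE),
    c("C1", "t2", TRUE),
    c("C2", "s1", FALSE), c("C2", "s3", FALSE), c("C2", "t2", TRUE),
    c("C3", "s4", FALSE),
    c("C4", "t3", TRUE), c("C4", "t4", TRUE), c("C4", "s5", FALSE),
    c("C5", "s1", FALSE), c("C5", "s2", FALSE), c("C5", "s6", FALSE),
    c("C6", "t4", TRUE)
  )
  data.frame(cave_id = vapply(rows, `[`, "", 1),
             species_id = vapply(rows, `[`, "", 2),
             troglobiont = as.logical(vapply(rows, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

toy_caves <- function() {
  data.frame(cave_id = paste0("C", 1:6),
             name = paste("cave", 1:6),
             x = c(100, 900, 1500, 2500, 3500, 3900),
             y = c(100, 200, 900, 1500, 2500, 2900),
             length_m = c(50, 120, 80, 300, 60, 40),
             season = c("dry", "wet", "dry", "wet", "dry", "unknown"),
             stringsAsFactors = FALSE)
}

# brute-force per-species scan: caves-per-species counts, the independent
# oracle for stenoendemism and singleton counting
bf_caves_per_species <- function(occ, troglobionts_only = TRUE) {
  o <- if (troglobionts_only) occ[occ$troglobiont, ] else occ
  sapply(split(o$cave_id, o$species_id), function(z) length(unique(z)))
}

# exhaustive contiguous-partition search: the independent oracle for the
# Fisher-Jenks dynamic program (feasible for n <= ~14)
bf_jenks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd_of <- function(idx) sum((x[idx] - mean(x[idx]))^2)
  if (k == 1) return(list(ssd = ssd_of(1:n), breaks = x[n]))
  best <- NULL
  for (cuts in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    bounds <- c(0, cuts, n)
    ssd <- sum(vapply(seq_len(k), function(j) {
      ssd_of((bounds[j] + 1):bounds[j + 1])
    }, numeric(1)))
    if (is.null(best) || ssd < best$ssd - 1e-12) {
      best <- list(ssd = ssd, pos = cuts)
    }
    # ties: combn enumerates in lexicographic order, so the first optimum
    # found already has lexicographically smallest break positions
  }
  list(ssd = best$ssd, breaks = x[c(best$pos, n)])
}

write_temp_csv <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}
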