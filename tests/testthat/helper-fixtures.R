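# Shared fixture builders: everything is generated in code at test time.

# random spectra matrix (descending grid 10 -> 0)
rand_matrix <- function(n, p, seed = 1, positive = FALSE) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  if (positive) X <- abs(X) + 0.1
  spectra_matrix(X, seq(10, 0.5, length.out = p),
                 sprintf("S%03d", seq_len(n)))
}

centered <- function(m) {
  spectra_matrix(sweep(m$X, 2, colMeans(m$X)), m$ppm, sample_ids(m))
}

# truncated SVD oracle for PCA: scores/loadings with the same sign
# convention (largest-|loading| entry positive)
svd_pca_oracle <- function(X, A) {
  s <- svd(scale(X, center = TRUE, scale = FALSE))
  P <- s$v[, seq_len(A), drop = FALSE]
  Tm <- s$u[, seq_len(A), drop = FALSE] %*% diag(s$d[seq_len(A)], A, A)
  for (a in seq_len(A)) {
    if (P[which.max(abs(P[, a])), a] < 0) {
      P[, a] <- -P[, a]; Tm[, a] <- -Tm[, a]
    }
  }
  list(scores = Tm, loadings = P)
}

# write a minimal AFFN JCAMP file from explicit header fields and Y values
write_affn_fixture <- function(path, firstx, lastx, npoints, yvalues,
                               yfactor = 1, extra = character(0),
                               drop_labels = character(0)) {
  hdr <- c("##TITLE=fixture", "##JCAMP-DX=4.24",
           sprintf("##FIRSTX=%g", firstx), sprintf("##LASTX=%g", lastx),
           sprintf("##NPOINTS=%d", npoints), sprintf("##YFACTOR=%g", yfactor),
           extra, "##XYDATA=(X++(Y..Y))")
  keep <- !vapply(hdr, function(l) any(startsWith(l, paste0("##", drop_labels, "="))),
                  logical(1))
  body <- paste(c(sprintf("%g", firstx), sprintf("%g", yvalues)), collapse = " ")
  writeLines(c(hdr[keep], body, "##END="), path)
  path
}

# Bruker processed-directory fixture from raw int32 values
write_bruker_fixture <- function(dir, ints, offset = 10, sw_p = 5000,
                                 sf = 500, nc_proc = 0, bytordp = 0,
                                 si = length(ints), drop_keys = character(0),
                                 truncate_1r = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keys <- c(OFFSET = offset, SW_p = sw_p, SF = sf, SI = si,
            BYTORDP = bytordp, NC_proc = nc_proc)
  keys <- keys[!names(keys) %in% drop_keys]
  writeLines(sprintf("##$%s= %g", names(keys), keys), file.path(dir, "procs"))
  con <- file(file.path(dir, "1r"), "wb")
  writeBin(as.integer(ints), con, size = 4,
           endian = if (bytordp == 0) "little" else "big")
  if (truncate_1r) {
    close(con)
    raw <- readBin(file.path(dir, "1r"), "raw", n = 4 * length(ints))
    con2 <- file(file.path(dir, "1r"), "wb")
    writeBin(raw[-1], con2)
    close(con2)
    return(dir)
  }
  close(con)
  dir
}

# small two-class cohort with one biomarker; defaults kept light for tests
# The biomarker (glycine) gets a tight within-class concentration range so
# a multiplicative class effect of 2-3 separates the class-conditional
# distributions; other compounds keep the default 4-fold spread.
small_cohort <- function(seed = 1, n_per_class = 15, multiplier = 3,
                         noise_sd = 0, shift_jitter_sd = 0,
                         grid = c(9.5, 0.5, 400)) {
  simulate_dataset(sim_config(
    n_classes = 2, n_per_class = n_per_class,
    biomarkers = list(glycine = c(1, multiplier)),
    conc_range = list(glycine = c(0.8, 1.25)),
    shift_jitter_sd = shift_jitter_sd, noise_sd = noise_sd,
    grid = grid, seed = seed))
}
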