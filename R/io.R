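# Spectral input/output: JCAMP-DX, Bruker processed directories, TSV matrices
# and annotation tables. All text I/O is UTF-8 with "." as decimal separator.

# ---------------------------------------------------------------------------
# JCAMP-DX

# ASDF pseudo-digit tables (JCAMP-DX compressed ordinate forms)
.sqz_pos <- c("@" = 0, A = 1, B = 2, C = 3, D = 4, E = 5, F = 6, G = 7, H = 8, I = 9)
.sqz_neg <- c(a = -1, b = -2, c = -3, d = -4, e = -5, f = -6, g = -7, h = -8, i = -9)
.dif_pos <- c("%" = 0, J = 1, K = 2, L = 3, M = 4, N = 5, O = 6, P = 7, Q = 8, R = 9)
.dif_neg <- c(j = -1, k = -2, l = -3, m = -4, n = -5, o = -6, p = -7, q = -8, r = -9)
.dup_dig <- c(S = 1, T = 2, U = 3, V = 4, W = 5, X = 6, Y = 7, Z = 8, s = 9)

# Tokenize the ordinate part of one JCAMP data line into a list of
# (type = "affn"|"sqz"|"dif"|"dup", value). Pseudo-digit carries the leading
# digit (and sign); trailing plain digits extend the magnitude.
.asdf_tokens <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  grab_digits <- function(i) {
    j <- i
    while (j <= n && chars[j] >= "0" && chars[j] <= "9") j <- j + 1L
    j
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", ",", ";")) { i <- i + 1L; next }
    if (ch %in% c("+", "-", ".") || (ch >= "0" && ch <= "9")) {
      # AFFN number (possibly with exponent)
      j <- i + 1L
      while (j <= n && (chars[j] %in% c(".", "E", "e") ||
                        (chars[j] >= "0" && chars[j] <= "9") ||
                        (chars[j] %in% c("+", "-") && chars[j - 1L] %in% c("E", "e"))))
        j <- j + 1L
      toks[[length(toks) + 1L]] <-
        list(type = "affn", value = as.numeric(paste(chars[i:(j - 1L)], collapse = "")))
      i <- j
    } else if (ch %in% names(.sqz_pos) || ch %in% names(.sqz_neg)) {
      lead <- if (ch %in% names(.sqz_pos)) .sqz_pos[[ch]] else .sqz_neg[[ch]]
      j <- grab_digits(i + 1L)
      tail_dig <- if (j > i + 1L) paste(chars[(i + 1L):(j - 1L)], collapse = "") else ""
      val <- as.numeric(paste0(if (lead < 0) "-" else "", abs(lead), tail_dig))
      toks[[length(toks) + 1L]] <- list(type = "sqz", value = val)
      i <- j
    } else if (ch %in% names(.dif_pos) || ch %in% names(.dif_neg)) {
      lead <- if (ch %in% names(.dif_pos)) .dif_pos[[ch]] else .dif_neg[[ch]]
      j <- grab_digits(i + 1L)
      tail_dig <- if (j > i + 1L) paste(chars[(i + 1L):(j - 1L)], collapse = "") else ""
      val <- as.numeric(paste0(if (lead < 0) "-" else "", abs(lead), tail_dig))
      toks[[length(toks) + 1L]] <- list(type = "dif", value = val)
      i <- j
    } else if (ch %in% names(.dup_dig)) {
      j <- grab_digits(i + 1L)
      tail_dig <- if (j > i + 1L) paste(chars[(i + 1L):(j - 1L)], collapse = "") else ""
      toks[[length(toks) + 1L]] <-
        list(type = "dup", value = as.numeric(paste0(.dup_dig[[ch]], tail_dig)))
      i <- j
    } else if (ch == "?") {
      stop("JCAMP parse error: '?' (missing ordinate) not supported")
    } else {
      stop(sprintf("JCAMP parse error: unexpected character '%s' in data line", ch))
    }
  }
  toks
}

#' Read a JCAMP-DX 1D spectrum
#'
#' Parses a single-spectrum JCAMP-DX 4.24/5.x file whose `##XYDATA` record is
#' the `(X++(Y..Y))` form, with ordinates in AFFN or in SQZ/DIF/DUP compressed
#' (ASDF) form, including the per-line Y-value checkpoints of the DIF form.
#' The ppm axis is reconstructed from `FIRSTX`/`LASTX`/`NPOINTS` and scaled by
#' `XFACTOR` where X values are raw; intensities are scaled by `YFACTOR`.
#' PAC and NTUPLES dialects are rejected with an explanatory error.
#'
#' @param path Path to a `.jdx`/`.dx` file.
#' @param sample_id Sample identifier; defaults to the file basename without
#'   extension.
#' @return An [nmr_spectrum].
#' @export
read_jcamp <- function(path, sample_id = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # strip $$ comments
  lines <- sub("\\$\\$.*$", "", lines)
  ldr_at <- grep("^##", lines)
  if (any(grepl("^##NTUPLES", lines)))
    stop("JCAMP parse error: NTUPLES dialect is not supported (single-spectrum (X++(Y..Y)) files only)")
  get_ldr <- function(label) {
    hit <- grep(paste0("^##", label, "="), lines)
    if (length(hit) == 0) return(NULL)
    sub(paste0("^##", label, "="), "", lines[hit[1]])
  }
  need <- function(label) {
    v <- get_ldr(label)
    if (is.null(v)) stop(sprintf("JCAMP parse error: required label ##%s= missing", label))
    v
  }
  xy_at <- grep("^##XYDATA=", lines)
  if (length(xy_at) == 0) stop("JCAMP parse error: required label ##XYDATA= missing")
  form <- trimws(sub("^##XYDATA=", "", lines[xy_at[1]]))
  if (!identical(gsub(" ", "", form), "(X++(Y..Y))"))
    stop(sprintf("JCAMP parse error: XYDATA form '%s' not supported, expected (X++(Y..Y)) (PAC/other dialects rejected)", form))
  npoints <- as.integer(need("NPOINTS"))
  firstx <- as.numeric(need("FIRSTX"))
  lastx <- as.numeric(need("LASTX"))
  yfactor <- as.numeric(get_ldr("YFACTOR") %||% "1")
  # data lines: from after ##XYDATA= to the next ## record (or ##END=)
  stop_at <- ldr_at[ldr_at > xy_at[1]]
  data_lines <- lines[(xy_at[1] + 1L):(if (length(stop_at)) stop_at[1] - 1L else length(lines))]
  data_lines <- trimws(data_lines)
  data_lines <- data_lines[nzchar(data_lines)]

  y_raw <- numeric(0)
  last_was_dif <- FALSE
  for (ln in data_lines) {
    toks <- .asdf_tokens(ln)
    if (length(toks) < 2L)
      stop("JCAMP parse error: data line without ordinates")
    # first token is the abscissa (raw X); ignored for the axis, which is
    # reconstructed from FIRSTX/LASTX/NPOINTS
    toks <- toks[-1L]
    first_ordinate <- TRUE
    prev_type <- NA_character_
    prev_dif <- NA_real_
    for (tk in toks) {
      if (tk$type == "dup") {
        if (is.na(prev_type) || prev_type == "dup")
          stop("JCAMP parse error: DUP with no preceding value")
        reps <- tk$value - 1L  # count includes the original occurrence
        if (reps < 0) stop("JCAMP parse error: DUP count < 1")
        for (r in seq_len(reps)) {
          if (prev_type == "dif") {
            y_raw <- c(y_raw, y_raw[length(y_raw)] + prev_dif)
          } else {
            y_raw <- c(y_raw, y_raw[length(y_raw)])
          }
        }
        if (prev_type == "dif") last_was_dif <- TRUE
        next
      }
      if (tk$type == "dif") {
        if (length(y_raw) == 0) stop("JCAMP parse error: DIF with no previous ordinate")
        y_raw <- c(y_raw, y_raw[length(y_raw)] + tk$value)
        prev_type <- "dif"; prev_dif <- tk$value
        last_was_dif <- TRUE
        first_ordinate <- FALSE
        next
      }
      # affn or sqz: absolute ordinate
      if (first_ordinate && last_was_dif) {
        # Y-value checkpoint: duplicates the final ordinate of the previous line
        if (tk$value != y_raw[length(y_raw)])
          stop(sprintf("JCAMP integrity error: DIF checkpoint %g does not match previous ordinate %g",
                       tk$value, y_raw[length(y_raw)]))
      } else {
        y_raw <- c(y_raw, tk$value)
      }
      prev_type <- tk$type
      last_was_dif <- FALSE
      first_ordinate <- FALSE
    }
  }
  if (length(y_raw) != npoints)
    stop(sprintf("JCAMP integrity error: NPOINTS=%d but %d ordinates decoded",
                 npoints, length(y_raw)))
  ppm <- seq(firstx, lastx, length.out = npoints)
  meta <- list(source = path)
  freq <- get_ldr(".OBSERVE FREQUENCY") %||% get_ldr("OBSERVEFREQUENCY")
  if (!is.null(freq)) meta$frequency_mhz <- trimws(freq)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  nmr_spectrum(sample_id, ppm, y_raw * yfactor, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectrum as JCAMP-DX
#'
#' Emits a minimal single-spectrum `(X++(Y..Y))` JCAMP-DX file. Ordinates are
#' written either in plain AFFN or in the SQZ/DIF/DUP compressed form with
#' per-line Y checkpoints (the dialect [read_jcamp] consumes), after division
#' by `yfactor` and rounding to integers in the compressed case.
#'
#' @param spectrum An [nmr_spectrum].
#' @param path Output file path.
#' @param compress One of `"affn"` or `"difdup"`.
#' @param yfactor Ordinate scale factor written as `##YFACTOR=`; raw stored
#'   ordinates are `intensity / yfactor` (rounded for `"difdup"`).
#' @return `path`, invisibly.
#' @export
write_jcamp <- function(spectrum, path, compress = c("affn", "difdup"),
                        yfactor = 1) {
  compress <- match.arg(compress)
  ppm <- spectrum$ppm
  y <- spectrum$intensity / yfactor
  n <- length(y)
  hdr <- c(
    sprintf("##TITLE=%s", spectrum$sample_id),
    "##JCAMP-DX=5.01",
    "##DATA TYPE=NMR SPECTRUM",
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY",
    "##XFACTOR=1",
    sprintf("##YFACTOR=%.17g", yfactor),
    sprintf("##FIRSTX=%.17g", ppm[1]),
    sprintf("##LASTX=%.17g", ppm[n]),
    sprintf("##NPOINTS=%d", n),
    "##XYDATA=(X++(Y..Y))")
  body <- character(0)
  if (compress == "affn") {
    idx <- seq(1L, n, by = 8L)
    for (a in idx) {
      b <- min(a + 7L, n)
      body <- c(body, paste(c(sprintf("%.17g", ppm[a]),
                              sprintf("%.17g", y[a:b])), collapse = " "))
    }
  } else {
    y <- round(y)
    sqz_enc <- function(v) {
      s <- sprintf("%d", abs(v))
      lead <- as.integer(substr(s, 1, 1))
      ch <- if (v < 0) names(.sqz_neg)[lead] else names(.sqz_pos)[lead + 1L]
      paste0(ch, substr(s, 2, nchar(s)))
    }
    dif_enc <- function(v) {
      s <- sprintf("%d", abs(v))
      lead <- as.integer(substr(s, 1, 1))
      ch <- if (v < 0) names(.dif_neg)[lead] else names(.dif_pos)[lead + 1L]
      paste0(ch, substr(s, 2, nchar(s)))
    }
    dup_enc <- function(cnt) {
      s <- sprintf("%d", cnt)
      paste0(names(.dup_dig)[as.integer(substr(s, 1, 1))],
             substr(s, 2, nchar(s)))
    }
    per_line <- 10L
    a <- 1L
    first_line <- TRUE
    while (a <= n) {
      if (first_line) {
        b <- min(a + per_line - 1L, n)
        seg_start <- a
      } else {
        # line starts at the previous line's final ordinate (checkpoint)
        seg_start <- a - 1L
        b <- min(a + per_line - 2L, n)
      }
      toks <- sqz_enc(y[seg_start])
      if (b > seg_start) {
        difs <- diff(y[seg_start:b])
        rle_d <- rle(difs)
        for (k in seq_along(rle_d$values)) {
          toks <- c(toks, dif_enc(rle_d$values[k]))
          if (rle_d$lengths[k] > 1L) toks <- c(toks, dup_enc(rle_d$lengths[k]))
        }
      }
      body <- c(body, paste(c(sprintf("%.17g", ppm[seg_start]), toks), collapse = ""))
      a <- b + 1L
      first_line <- FALSE
    }
  }
  writeLines(c(hdr, body, "##END="), path, useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Bruker processed data (procs + 1r)

#' Read a Bruker processed-spectrum directory
#'
#' Reads a directory containing the parameter file `procs` and the binary
#' intensity file `1r`. Intensities are the int32 values of `1r` (byte order
#' per `BYTORDP`: 0 = little-endian, 1 = big-endian) multiplied by
#' `2^NC_proc`. The ppm axis descends from `OFFSET` over a width of
#' `SW_p / SF` ppm in `SI` points.
#'
#' @param dir Directory containing `procs` and `1r`.
#' @param sample_id Sample identifier; defaults to the directory basename.
#' @return An [nmr_spectrum].
#' @export
read_bruker <- function(dir, sample_id = NULL) {
  procs_path <- file.path(dir, "procs")
  r_path <- file.path(dir, "1r")
  if (!file.exists(procs_path)) stop("Bruker parse error: missing procs file in ", dir)
  if (!file.exists(r_path)) stop("Bruker parse error: missing 1r file in ", dir)
  lines <- readLines(procs_path, warn = FALSE)
  get_par <- function(key) {
    hit <- grep(paste0("^##\\$", key, "="), lines)
    if (length(hit) == 0)
      stop(sprintf("Bruker parse error: procs key $%s missing", key))
    as.numeric(trimws(sub(paste0("^##\\$", key, "="), "", lines[hit[1]])))
  }
  offset <- get_par("OFFSET")
  sw_p <- get_par("SW_p")
  sf <- get_par("SF")
  si <- as.integer(get_par("SI"))
  bytordp <- get_par("BYTORDP")
  nc_proc <- get_par("NC_proc")
  nbytes <- file.size(r_path)
  if (nbytes != 4L * si)
    stop(sprintf("Bruker integrity error: 1r has %d bytes, expected 4*SI = %d",
                 nbytes, 4L * si))
  con <- file(r_path, "rb")
  on.exit(close(con))
  raw_int <- readBin(con, what = "integer", n = si, size = 4L,
                     endian = if (bytordp == 0) "little" else "big")
  intensity <- raw_int * 2^nc_proc
  width <- sw_p / sf
  ppm <- seq(offset, offset - width, length.out = si)
  if (is.null(sample_id)) sample_id <- basename(normalizePath(dir))
  nmr_spectrum(sample_id, ppm, intensity,
               meta = list(source = dir, frequency_mhz = as.character(sf)))
}

# ---------------------------------------------------------------------------
# Grid alignment

#' Align spectra onto a common ppm grid
#'
#' Linear interpolation of each spectrum onto a shared descending grid so that
#' spectra from heterogeneous sources form one variable axis. Grid points
#' outside a spectrum's ppm range are zero-filled (with a warning) under the
#' default policy, or raise an error under `out_of_range = "error"`.
#' Duplicate sample ids get a numeric suffix with a warning.
#'
#' @param spectra List of [nmr_spectrum] objects.
#' @param grid Strictly descending numeric ppm grid.
#' @param out_of_range `"zero-fill"` (default) or `"error"`.
#' @return A [spectra_matrix] with one row per input spectrum.
#' @export
align_to_grid <- function(spectra, grid, out_of_range = c("zero-fill", "error")) {
  out_of_range <- match.arg(out_of_range)
  if (length(spectra) == 0) stop("empty spectrum list")
  grid <- as.numeric(grid)
  if (length(grid) < 2L || !all(diff(grid) < 0))
    stop("grid must be strictly descending with >= 2 points")
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) {
    warning("duplicate sample ids renamed with numeric suffixes")
    ids <- make.unique(ids, sep = "_")
  }
  X <- matrix(0, nrow = length(spectra), ncol = length(grid))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    xa <- rev(s$ppm)           # ascending for approx()
    ya <- rev(s$intensity)
    outside <- grid > max(xa) | grid < min(xa)
    if (any(outside)) {
      if (out_of_range == "error")
        stop(sprintf("spectrum '%s' does not cover the grid (%d points outside)",
                     s$sample_id, sum(outside)))
      warning(sprintf("spectrum '%s': %d grid points outside its ppm range zero-filled",
                      s$sample_id, sum(outside)))
    }
    yi <- stats::approx(xa, ya, xout = grid, method = "linear", rule = 1)$y
    yi[is.na(yi)] <- 0
    X[i, ] <- yi
  }
  spectra_matrix(X, grid, ids)
}

# ---------------------------------------------------------------------------
# TSV matrix dialect: '#' comment lines, then a header row `sample_id` followed
# by the ppm values, then one row per sample. No quoting; "." decimal only.

fmt17 <- function(x) sprintf("%.17g", x)

#' Read a spectral matrix from TSV
#'
#' @param path TSV file in the canonical dialect: optional leading `#` comment
#'   lines, a header row `sample_id` followed by ppm values, one row per
#'   sample, tab-separated, no quoting.
#' @return A [spectra_matrix].
#' @export
read_tsv_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("TSV matrix needs a header and at least one sample row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1]]
  if (hdr[1] != "sample_id") stop("TSV matrix header must start with 'sample_id'")
  ppm <- suppressWarnings(as.numeric(hdr[-1]))
  if (anyNA(ppm)) stop("non-numeric ppm value in header at column ",
                       which(is.na(ppm))[1] + 1L)
  p <- length(ppm)
  rows <- fields[-1]
  ids <- character(length(rows))
  X <- matrix(NA_real_, nrow = length(rows), ncol = p)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != p + 1L)
      stop(sprintf("ragged row %d: %d fields, expected %d", i, length(r), p + 1L))
    ids[i] <- r[1]
    vals <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      stop(sprintf("non-numeric cell at row %d, column %d ('%s')", i, j + 1L, r[j + 1L]))
    }
    X[i, ] <- vals
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate sample id in TSV: ", paste(unique(dup), collapse = ", "))
  spectra_matrix(X, ppm, ids)
}

#' Write a spectral matrix as TSV
#'
#' Inverse of [read_tsv_matrix]; numbers are printed with 17 significant
#' digits so the round-trip is lossless for finite doubles.
#'
#' @param m A [spectra_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(m, path) {
  hdr <- paste(c("sample_id", fmt17(m$ppm)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m$X)), function(i) {
    paste(c(rownames(m$X)[i], fmt17(m$X[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Annotations

#' Read a sample annotation table
#'
#' TSV with a header containing at least `sample_id` and `class`; any further
#' columns are carried along as string covariates.
#'
#' @param path Annotation TSV path.
#' @return A data frame with character columns, first two `sample_id` and
#'   `class`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = "character", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  for (col in c("sample_id", "class"))
    if (!col %in% names(df))
      stop(sprintf("annotation file missing mandatory column '%s'", col))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0)
    stop("duplicate sample_id in annotations: ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(df$class)))
    stop("empty class label for sample(s): ",
         paste(df$sample_id[!nzchar(df$class)], collapse = ", "))
  df[, c("sample_id", "class", setdiff(names(df), c("sample_id", "class")))]
}

#' Write a sample annotation table
#' @param annotations Data frame with `sample_id` and `class` columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
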