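#' Read a protein FASTA file
#'
#' Headers are parsed to the first whitespace as the record id; sequences are
#' uppercased and validated against the 20 canonical one-letter codes, with
#' the record and position reported on failure.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    res <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    bad <- which(!res %in% canonical_residues())
    if (length(bad) > 0L) {
      stop("non-canonical residue '", res[bad[1]], "' in record '", ids[i],
           "' at position ", bad[1])
    }
  }
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (id in names(sequences)) {
    s <- sequences[[id]]
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", id), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Read a Mascot Generic Format (MGF) spectrum file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, `CHARGE` (the
#' `"3+"` dialect is accepted), `TITLE` and `SCANS` headers plus peak lines.
#' Peaks are sorted by m/z. Spectra lacking a charge get `charge = NA` and
#' are flagged.
#'
#' @param path Path to an MGF file.
#' @return List of spectrum records: each a list with `scan_id`,
#'   `precursor_mz`, `charge`, `peaks` (data.frame `mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  spectra <- list()
  i <- 1L; n <- length(lines); scan_no <- 0L
  while (i <= n) {
    line <- trimws(lines[i])
    if (identical(line, "BEGIN IONS")) {
      begin_line <- i
      scan_no <- scan_no + 1L
      title <- NULL; pepmass <- NA_real_; charge <- NA_integer_; scans <- NULL
      mz <- numeric(0); intensity <- numeric(0)
      i <- i + 1L
      closed <- FALSE
      while (i <= n) {
        l <- trimws(lines[i])
        if (identical(l, "END IONS")) { closed <- TRUE; break }
        if (grepl("^PEPMASS=", l)) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", l), "\\s+")[[1]][1])
        } else if (grepl("^CHARGE=", l)) {
          ch <- sub("^CHARGE=", "", l)
          sign <- if (grepl("-", ch, fixed = TRUE)) -1L else 1L
          charge <- sign * as.integer(gsub("[^0-9]", "", ch))
        } else if (grepl("^TITLE=", l)) {
          title <- sub("^TITLE=", "", l)
        } else if (grepl("^SCANS=", l)) {
          scans <- sub("^SCANS=", "", l)
        } else if (grepl("^[0-9]", l)) {
          parts <- strsplit(l, "[\t ]+")[[1]]
          mz <- c(mz, as.numeric(parts[1]))
          intensity <- c(intensity, if (length(parts) > 1L) as.numeric(parts[2]) else 0)
        }
        i <- i + 1L
      }
      if (!closed) {
        stop("unterminated BEGIN IONS block starting at line ", begin_line)
      }
      ord <- order(mz)
      scan_id <- if (!is.null(title)) title
                 else if (!is.null(scans)) paste0("scan_", scans)
                 else paste0("index_", scan_no)
      spectra[[length(spectra) + 1L]] <- list(
        scan_id = scan_id, precursor_mz = pepmass, charge = charge,
        peaks = data.frame(mz = mz[ord], intensity = intensity[ord]))
    }
    i <- i + 1L
  }
  n_nochg <- sum(vapply(spectra, function(s) is.na(s$charge), logical(1)))
  if (n_nochg > 0L) message(n_nochg, " spectrum/spectra lack a charge")
  spectra
}

#' Write spectra to MGF
#'
#' @param spectra Spectrum list as returned by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con, sep = "\n")
    writeLines(paste0("TITLE=", sp$scan_id), con, sep = "\n")
    writeLines(sprintf("PEPMASS=%.9f", sp$precursor_mz), con, sep = "\n")
    if (!is.null(sp$charge) && !is.na(sp$charge)) {
      writeLines(sprintf("CHARGE=%d+", sp$charge), con, sep = "\n")
    }
    if (!is.null(sp$peaks) && nrow(sp$peaks) > 0L) {
      writeLines(sprintf("%.9f %.6f", sp$peaks$mz, sp$peaks$intensity),
                 con, sep = "\n")
    }
    writeLines(c("END IONS", ""), con, sep = "\n")
  }
  invisible(path)
}

#' Read / write the package's tab-separated tables
#'
#' TSV with header, '.' decimal separator, UTF-8, LF line endings.
#'
#' @param path File path.
#' @return `read_tsv_table()`: a data.frame. `write_tsv_table()`: `path`,
#'   invisibly.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param x Data.frame to write.
#' @export
write_tsv_table <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Validated container of every tunable threshold; the defaults are the
#' printed constants of the adduct-mapping screen (pseudocount 0.1, volcano
#' gates x >= 2 and y >= 1.3, probability cutoffs 90% / 99.9%, minimum 2
#' PSMs) plus Orbitrap-class tolerances.
#'
#' @param ... Named overrides of the defaults.
#' @return A validated named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    pseudocount = 0.1, x_min = 2, y_min = 1.3,
    peptide_prob_min = 0.9, protein_prob_min = 0.999, min_psms = 2,
    ms1_ppm = 10, ms2_ppm = 20,
    max_missed = 3, min_len = 4, max_len = 60,
    log_base_y = "log10", test = "student", seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  with(cfg, {
    if (pseudocount <= 0) stop("config field 'pseudocount' must be > 0")
    if (peptide_prob_min < 0 || peptide_prob_min > 1)
      stop("config field 'peptide_prob_min' must be in [0,1]")
    if (protein_prob_min < 0 || protein_prob_min > 1)
      stop("config field 'protein_prob_min' must be in [0,1]")
    if (min_psms < 1) stop("config field 'min_psms' must be >= 1")
    if (ms1_ppm <= 0 || ms2_ppm <= 0)
      stop("config fields 'ms1_ppm'/'ms2_ppm' must be > 0")
    if (max_missed < 0) stop("config field 'max_missed' must be >= 0")
    if (min_len < 1 || max_len < min_len)
      stop("config fields 'min_len'/'max_len' invalid")
    if (!log_base_y %in% c("log10", "ln"))
      stop("config field 'log_base_y' must be 'log10' or 'ln'")
    if (!test %in% c("student", "welch"))
      stop("config field 'test' must be 'student' or 'welch'")
  })
  structure(cfg, class = "run_config")
}
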