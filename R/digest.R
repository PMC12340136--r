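#' In-silico tryptic digestion
#'
#' Strict trypsin specificity: cleavage C-terminal to K or R, suppressed when
#' the following residue is P. All peptides carrying 0..`max_missed` internal
#' (missed) cleavage sites are enumerated, then length-filtered. Coordinates
#' are 1-based inclusive in the parent protein.
#'
#' @param protein Named length-1 character vector or list with `id` and
#'   `residues`; a plain string is accepted (id `"protein"`).
#' @param max_missed Maximum internal missed-cleavage sites (default 3).
#' @param min_len,max_len Peptide length bounds (defaults 4 and 60).
#' @return A data.frame with columns `parent_id`, `start`, `end`, `sequence`,
#'   `missed_cleavages`, `n_cys` and a list column `cys_positions` (1-based
#'   protein coordinates of cysteines), ordered by `start` then `end`.
#' @examples
#' digest_trypsin("MKCR", max_missed = 1, min_len = 1)
#' @export
digest_trypsin <- function(protein, max_missed = 3, min_len = 4, max_len = 60) {
  p <- as_protein(protein)
  res <- strsplit(p$residues, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% canonical_residues())
  if (length(bad) > 0L) {
    stop("non-canonical residue '", res[bad[1]], "' in protein '", p$id,
         "' at position ", bad[1])
  }
  n <- length(res)
  stopifnot(max_missed >= 0, min_len >= 1, max_len >= min_len)

  # cleavage sites: after position i when res[i] is K/R and res[i+1] is not P
  sites <- which(res %in% c("K", "R"))
  sites <- sites[sites < n & res[pmin(sites + 1L, n)] != "P"]
  bounds <- c(0L, sites, n)
  nb <- length(bounds)

  out <- list()
  k <- 0L
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + max_missed)) {
      start <- bounds[i] + 1L
      end <- bounds[j]
      len <- end - start + 1L
      if (len < min_len || len > max_len) next
      k <- k + 1L
      out[[k]] <- list(start = start, end = end, missed = j - i - 1L)
    }
  }
  if (k == 0L) {
    return(empty_peptide_table(p$id))
  }
  start <- vapply(out, `[[`, integer(1), "start")
  end <- vapply(out, `[[`, integer(1), "end")
  missed <- vapply(out, `[[`, integer(1), "missed")
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]; missed <- missed[ord]
  seqs <- substring(p$residues, start, end)
  cys <- lapply(seq_along(start), function(i) {
    pos <- which(res[start[i]:end[i]] == "C")
    if (length(pos) == 0L) integer(0) else start[i] + pos - 1L
  })
  data.frame(
    parent_id = p$id, start = start, end = end, sequence = seqs,
    missed_cleavages = missed,
    n_cys = lengths(cys),
    cys_positions = I(cys),
    stringsAsFactors = FALSE
  )
}

empty_peptide_table <- function(parent_id = character(0)) {
  data.frame(parent_id = character(0), start = integer(0), end = integer(0),
             sequence = character(0), missed_cleavages = integer(0),
             n_cys = integer(0), cys_positions = I(list()),
             stringsAsFactors = FALSE)
}

as_protein <- function(protein) {
  if (is.list(protein) && !is.null(protein$residues)) {
    list(id = if (is.null(protein$id)) "protein" else protein$id,
         residues = toupper(protein$residues))
  } else if (is.character(protein) && length(protein) == 1L) {
    id <- if (is.null(names(protein)) || !nzchar(names(protein))) "protein" else names(protein)
    list(id = id, residues = toupper(unname(protein)))
  } else {
    stop("protein must be a single sequence string or a list(id, residues)")
  }
}

#' Cysteine-containing peptides
#'
#' Subset of a digest that carries at least one cysteine; `cys_positions` are
#' 1-based coordinates in the parent protein.
#'
#' @param peptides A peptide table from [digest_trypsin()].
#' @return The subset of rows with `n_cys >= 1`.
#' @export
cysteine_peptides <- function(peptides) {
  stopifnot(is.data.frame(peptides), "n_cys" %in% names(peptides))
  out <- peptides[peptides$n_cys >= 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
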