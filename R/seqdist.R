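# Alignment handling, haplotype collapsing and uncorrected p-distances.

iupac_ok <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-", "?")

#' Construct a validated, normalized alignment
#'
#' Builds a `dna_alignment` from a character matrix (one row per record,
#' one column per site): uppercased, U mapped to T, and checked against the
#' IUPAC DNA alphabet (plus `-` and `?`).
#'
#' @param m character matrix; rownames are used as record ids (generated if
#'   absent).
#' @return a `dna_alignment`.
#' @export
new_alignment <- function(m) {
  stopifnot(is.matrix(m), is.character(m))
  m <- toupper(m)
  m[m == "U"] <- "T"
  bad <- setdiff(unique(as.vector(m)), iupac_ok)
  if (length(bad)) {
    stop("illegal character(s) in alignment: ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  class(m) <- c("dna_alignment", class(m))
  m
}

#' @export
`[.dna_alignment` <- function(x, ...) {
  out <- NextMethod()
  if (is.matrix(out) && is.character(out)) {
    class(out) <- c("dna_alignment", "matrix", "array")
  }
  out
}

#' Read a FASTA alignment
#'
#' All sequences must have the same length (it is an alignment, not a
#' sequence set). Sequences are normalized to uppercase with U mapped to T;
#' any character outside the IUPAC DNA alphabet (plus `-` and `?`) is an
#' error.
#'
#' @param file path to a FASTA file.
#' @return a `dna_alignment`: character matrix with one row per record,
#'   rownames = record ids.
#' @export
read_fasta <- function(file) {
  if (!file.exists(file)) stop("FASTA file not found: ", file, call. = FALSE)
  ss <- tryCatch(Biostrings::readBStringSet(file, format = "fasta"),
                 error = function(e)
                   stop("could not parse FASTA: ", conditionMessage(e),
                        call. = FALSE))
  if (!length(ss)) stop("empty FASTA file", call. = FALSE)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(sort(unique(w)), collapse = ", "), call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(ss))
  m <- do.call(rbind, strsplit(as.character(ss), "", fixed = TRUE))
  rownames(m) <- ids
  new_alignment(m)
}

#' Write an alignment to FASTA
#'
#' @param aln a `dna_alignment`.
#' @param file output path.
#' @export
write_fasta <- function(aln, file) {
  stopifnot(inherits(aln, "dna_alignment"))
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1L, paste, collapse = "")
  writeLines(lines, file)
  invisible(file)
}

#' Collapse identical sequences to haplotypes
#'
#' One representative (the first occurrence) is kept per distinct sequence
#' string; the returned map records which input records each representative
#' stands for. Identity is exact string equality after normalization;
#' collapsing is idempotent.
#'
#' @param aln a `dna_alignment`.
#' @return list with `alignment` (the collapsed `dna_alignment`) and `map`
#'   (named list: representative id -> character vector of member ids).
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  key <- apply(aln, 1L, paste, collapse = "")
  first <- !duplicated(key)
  reps <- rownames(aln)[first]
  map <- lapply(key[first], function(k) rownames(aln)[key == k])
  names(map) <- reps
  out <- aln[first, , drop = FALSE]
  class(out) <- class(aln)
  list(alignment = out, map = map)
}

#' Pairwise uncorrected p-distances with pairwise deletion
#'
#' For each pair of sequences, only sites where both symbols are an
#' unambiguous A, C, G or T are compared (gaps, N and IUPAC ambiguity codes
#' are excluded pair by pair); the distance is the proportion of compared
#' sites that differ. A pair with zero comparable sites gets a missing
#' distance with a warning.
#'
#' @param aln a `dna_alignment` with at least 2 sequences.
#' @return list of class `p_distance_matrix` with `d` (symmetric distance
#'   matrix, zero diagonal) and `sites` (per-pair compared-site counts).
#' @export
p_distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (nrow(aln) < 2L) stop("need at least 2 sequences", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  V <- matrix(0, nrow(aln), ncol(aln))
  match_cnt <- matrix(0, nrow(aln), nrow(aln))
  for (b in bases) {
    I <- (unclass(aln) == b) * 1
    V <- V + I
    match_cnt <- match_cnt + tcrossprod(I)
  }
  sites <- tcrossprod(V)
  d <- 1 - match_cnt / sites
  diag(d) <- 0
  if (any(sites[upper.tri(sites)] == 0)) {
    warning("pair(s) with zero comparable sites: distance undefined (NA)")
  }
  dimnames(d) <- dimnames(sites) <- list(rownames(aln), rownames(aln))
  structure(list(d = d, sites = sites), class = "p_distance_matrix")
}

#' Intra- and interspecific distance summaries over a species partition
#'
#' Pools all within-species pairs for the intraspecific maximum and 95th
#' percentile (linear-interpolation quantile) and all between-species pairs
#' for the interspecific minimum and maximum; also reports per-species
#' intraspecific maxima and 95th percentiles.
#'
#' @param dm a [p_distance_matrix()].
#' @param species_map named character vector: sequence id -> species id.
#'   Every sequence in `dm` must be assigned.
#' @return list of class `partition_distance_summary`: `per_species`
#'   (data.frame `species`, `n`, `intra_max`, `intra_p95`), `intra_max`,
#'   `intra_p95`, `inter_min`, `inter_max`, and the pooled pair vectors
#'   `intra` and `inter`.
#' @export
partition_distance_summary <- function(dm, species_map) {
  stopifnot(inherits(dm, "p_distance_matrix"))
  ids <- rownames(dm$d)
  if (!all(ids %in% names(species_map))) {
    stop("unassigned sequence(s): ",
         paste(setdiff(ids, names(species_map)), collapse = ", "),
         call. = FALSE)
  }
  sp <- species_map[ids]
  n <- length(ids)
  ut <- which(upper.tri(dm$d), arr.ind = TRUE)
  vals <- dm$d[ut]
  same <- sp[ut[, 1L]] == sp[ut[, 2L]]
  intra <- vals[same]
  inter <- vals[!same]
  per_species <- do.call(rbind, lapply(unique(sp), function(s) {
    v <- vals[same & sp[ut[, 1L]] == s]
    data.frame(species = s, n = sum(sp == s),
               intra_max = if (length(v)) max(v, na.rm = TRUE) else NA_real_,
               intra_p95 = if (length(v))
                 as.numeric(stats::quantile(v, 0.95, na.rm = TRUE,
                                            type = 7)) else NA_real_)
  }))
  rownames(per_species) <- NULL
  structure(list(
    per_species = per_species,
    intra_max = if (length(intra)) max(intra, na.rm = TRUE) else NA_real_,
    intra_p95 = if (length(intra))
      as.numeric(stats::quantile(intra, 0.95, na.rm = TRUE, type = 7))
      else NA_real_,
    inter_min = if (length(inter)) min(inter, na.rm = TRUE) else NA_real_,
    inter_max = if (length(inter)) max(inter, na.rm = TRUE) else NA_real_,
    intra = intra, inter = inter
  ), class = "partition_distance_summary")
}

#' @export
print.partition_distance_summary <- function(x, ...) {
  cat(sprintf(
    "p-distance summary: intra max %.4g (95%% <= %.4g), inter %.4g-%.4g\n",
    x$intra_max, x$intra_p95, x$inter_min, x$inter_max))
  invisible(x)
}
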