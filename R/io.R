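#' Read one assembly from a FASTA file
#'
#' Reads a (multi-record, optionally gzipped) FASTA file into a tibble of
#' sequence records for one sample. Residues are upper-cased; any character
#' outside `A/C/G/T/N` is replaced by `N` and the total number of replacements
#' is reported via a message. The record identifier is the first
#' whitespace-free token of the header line.
#'
#' @param path Path to a FASTA file.
#' @param sample_label Sample label attached to every record.
#' @return A tibble with columns `sample`, `seq_id`, `residues`.
#' @export
read_fasta <- function(path, sample_label) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("not a readable FASTA file: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate sequence id in sample '", sample_label, "': ", dup)
  }
  res <- toupper(as.character(set))
  if (any(nchar(res) == 0L)) {
    stop("record with empty sequence: ", ids[nchar(res) == 0L][1L])
  }
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", res), function(m) {
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1)))
  if (n_bad > 0L) {
    res <- gsub("[^ACGTN]", "N", res)
    inform(sprintf("%s: replaced %d non-ACGTN character(s) with N",
                   sample_label, n_bad))
  }
  tibble::tibble(sample = sample_label, seq_id = ids, residues = unname(res))
}

#' Write sequences to a FASTA file
#'
#' @param x A named character vector, `DNAStringSet`, or tibble with
#'   `seq_id`/`residues` columns.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(x, path, width = 60L) {
  Biostrings::writeXStringSet(as_dna_set(x), path, width = width)
  invisible(path)
}

#' Bundle assemblies from several samples
#'
#' A sample set holds the assemblies of every sample, with one of them marked
#' as the reference the SSR screen runs on.
#'
#' @param sequences Named list, one element per sample, each a tibble from
#'   [read_fasta()], a named character vector, or a `DNAStringSet`.
#' @param reference Label of the reference sample (must be in
#'   `names(sequences)`).
#' @return An object of class `polyssr_sample_set`.
#' @export
sample_set <- function(sequences, reference) {
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("`sequences` must be a fully named list (one name per sample)")
  }
  if (length(sequences) < 2L) stop("a sample set needs at least 2 samples")
  if (!reference %in% names(sequences)) {
    stop("reference sample '", reference, "' not among samples")
  }
  sets <- lapply(sequences, as_dna_set)
  for (s in names(sets)) {
    if (anyDuplicated(names(sets[[s]]))) {
      stop("duplicate seq_id within sample '", s, "'")
    }
  }
  structure(
    list(reference = reference, samples = names(sets), sequences = sets,
         renames = NULL),
    class = "polyssr_sample_set")
}

#' @export
print.polyssr_sample_set <- function(x, ...) {
  cat("<polyssr_sample_set> ", length(x$samples), " samples (reference: ",
      x$reference, ")\n", sep = "")
  for (s in x$samples) {
    cat("  ", s, ": ", length(x$sequences[[s]]), " sequence(s), ",
        sum(Biostrings::width(x$sequences[[s]])), " bp\n", sep = "")
  }
  invisible(x)
}

#' Rewrite sequence headers as "<sample>|<seq_id>"
#'
#' Prefixing every sequence id with its sample label makes ids globally unique
#' across the sample set, so that assemblies using identical contig names
#' (e.g. "chr1" in every genome) cannot collide downstream. The operation is
#' idempotent and the old-to-new mapping is retained in the `renames` field.
#'
#' @param ss A [sample_set()].
#' @return The sample set with rewritten ids.
#' @export
sanitize_headers <- function(ss) {
  stopifnot(inherits(ss, "polyssr_sample_set"))
  maps <- list()
  for (s in ss$samples) {
    old <- names(ss$sequences[[s]])
    prefix <- paste0(s, "|")
    new <- ifelse(startsWith(old, prefix), old, paste0(prefix, old))
    names(ss$sequences[[s]]) <- new
    maps[[s]] <- tibble::tibble(sample = s, old = old, new = new)
  }
  ss$renames <- dplyr::bind_rows(maps)
  ss
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `CDS`, `five_prime_UTR` and `three_prime_UTR` features and
#' groups them by gene (CDS/UTR features are attached to their gene through
#' the `Parent`/`ID` attribute chain, so both gene->CDS and gene->mRNA->CDS
#' layouts work). GFF 1-based inclusive coordinates are converted to the
#' package-internal 0-based half-open convention. CDS or UTR features falling
#' outside their gene span are dropped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `seq_id`, `strand`, `type`,
#'   `start`, `end` (0-based half-open).
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 9L)
  if (length(bad) > 0L) {
    stop("malformed GFF line ", lineno[bad[1L]], ": expected 9 columns, got ",
         lengths(rows)[bad[1L]])
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(gene_id = character(), seq_id = character(),
                          strand = character(), type = character(),
                          start = integer(), end = integer()))
  }
  feat <- tibble::tibble(
    seq_id = vapply(rows, `[[`, character(1), 1L),
    type = vapply(rows, `[[`, character(1), 3L),
    start = as.integer(vapply(rows, `[[`, character(1), 4L)) - 1L,
    end = as.integer(vapply(rows, `[[`, character(1), 5L)),
    strand = vapply(rows, `[[`, character(1), 7L),
    attr = vapply(rows, `[[`, character(1), 9L),
    line = lineno)
  if (anyNA(feat$start) || anyNA(feat$end)) {
    stop("malformed GFF coordinates at line ",
         feat$line[which(is.na(feat$start) | is.na(feat$end))[1L]])
  }
  attr_val <- function(attr, key) {
    pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
    m <- regexpr(pat, attr, perl = TRUE)
    out <- rep(NA_character_, length(attr))
    hit <- m > 0
    out[hit] <- sub(pat, "\\2", regmatches(attr, m)[seq_len(sum(hit))],
                    perl = TRUE)
    out
  }
  feat$id <- attr_val(feat$attr, "ID")
  feat$parent <- attr_val(feat$attr, "Parent")

  genes <- feat[feat$type == "gene", ]
  if (anyNA(genes$id)) stop("gene feature without ID attribute")
  parent_of <- setNames(feat$parent, feat$id)
  gene_ids <- genes$id
  resolve_gene <- function(id) {
    seen <- 0L
    while (!is.na(id) && !(id %in% gene_ids) && seen < 5L) {
      id <- unname(parent_of[id])
      seen <- seen + 1L
    }
    if (is.na(id) || !(id %in% gene_ids)) NA_character_ else id
  }
  sub_types <- c("CDS", "five_prime_UTR", "three_prime_UTR")
  subs <- feat[feat$type %in% sub_types, ]
  if (nrow(subs) > 0L) {
    anchor <- ifelse(!is.na(subs$parent), subs$parent, subs$id)
    subs$gene_id <- vapply(anchor, resolve_gene, character(1))
    orphan <- is.na(subs$gene_id)
    if (any(orphan)) {
      warn(sprintf("dropping %d CDS/UTR feature(s) with no resolvable gene",
                   sum(orphan)))
      subs <- subs[!orphan, ]
    }
    gstart <- setNames(genes$start, genes$id)
    gend <- setNames(genes$end, genes$id)
    gseq <- setNames(genes$seq_id, genes$id)
    outside <- subs$start < gstart[subs$gene_id] |
      subs$end > gend[subs$gene_id] | subs$seq_id != gseq[subs$gene_id]
    if (any(outside)) {
      warn(sprintf("dropping %d CDS/UTR feature(s) outside their gene span",
                   sum(outside)))
      subs <- subs[!outside, ]
    }
  } else {
    subs$gene_id <- character(0)
  }
  genes$gene_id <- genes$id
  out <- dplyr::bind_rows(
    genes[, c("gene_id", "seq_id", "strand", "type", "start", "end")],
    subs[, c("gene_id", "seq_id", "strand", "type", "start", "end")])
  dplyr::arrange(out, .data$seq_id, .data$start, .data$gene_id)
}
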