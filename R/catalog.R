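# Species registries and protein catalogs.
#
# A registry lists the species in a study (short code, binomial name,
# outgroup flag, and which single species anchors the reference
# nomenclature).  A catalog lists candidate family members: one row per
# gene model, with declared domain architecture, activity state and
# ortholog-group annotations where known.  Both are stored as tab-separated
# text with a fixed header.

REGISTRY_COLS <- c("code", "name", "is_outgroup", "is_reference_anchor")
CATALOG_COLS <- c("id", "species", "length_aa", "architecture", "prior_names",
                  "anchor_name", "active", "activity_reason", "not_family",
                  "group", "proposed_name")

#' Read a species registry
#'
#' @param path tab-separated file with columns `code`, `name`,
#'   `is_outgroup`, `is_reference_anchor` (0/1 flags).
#' @return a data frame of class `deg_registry`.
#' @export
read_registry <- function(path) {
  reg <- read_tsv_checked(path, REGISTRY_COLS)
  if (nrow(reg) == 0L) stop("registry is empty: ", path)
  if (anyDuplicated(reg$code))
    stop("duplicate species code in registry: ",
         reg$code[duplicated(reg$code)][1L])
  reg$is_outgroup <- as.logical(as.integer(reg$is_outgroup))
  reg$is_reference_anchor <- as.logical(as.integer(reg$is_reference_anchor))
  if (sum(reg$is_reference_anchor) != 1L)
    stop("exactly one registry species must be the reference anchor")
  class(reg) <- c("deg_registry", "data.frame")
  reg
}

#' Load a protein catalog with its species registry
#'
#' Reads one row per gene model.  Declared architecture strings are parsed
#' (and so validated) with [parse_architecture()]; rows flagged as probable
#' non-family members (`not_family` = 1) are retained but marked.
#'
#' @param path catalog TSV (see `degphylo_example("catalog_plants.tsv")`).
#' @param registry_path registry TSV.
#' @return an object of class `deg_catalog`: list with `registry`, `records`
#'   (data frame) and `provenance`.
#' @examples
#' cat5 <- load_catalog(degphylo_example("catalog_plants.tsv"),
#'                      degphylo_example("registry_plants.tsv"))
#' table(cat5$records$species)
#' @export
load_catalog <- function(path, registry_path) {
  registry <- read_registry(registry_path)
  rec <- read_tsv_checked(path, CATALOG_COLS)
  if (nrow(rec) == 0L) stop("catalog has no records: ", path)
  if (anyDuplicated(rec$id))
    stop("duplicate gene-model id in catalog: ",
         rec$id[duplicated(rec$id)][1L])
  bad <- setdiff(unique(rec$species), registry$code)
  if (length(bad))
    stop("species code not in registry: ", paste(bad, collapse = ", "))
  rec$length_aa <- as.integer(rec$length_aa)
  if (any(is.na(rec$length_aa) | rec$length_aa < 0))
    stop("length_aa must be a non-negative integer")
  rec$not_family <- as.logical(as.integer(ifelse(rec$not_family == "",
                                                 "0", rec$not_family)))
  rec$active <- ifelse(rec$active == "", NA, rec$active == "1")
  # validate declared architectures by parsing them
  for (a in rec$architecture[rec$architecture != ""]) parse_architecture(a)
  structure(list(registry = registry, records = rec,
                 provenance = paste("loaded from", path)),
            class = "deg_catalog")
}

#' Write a catalog (and its registry) back to TSV
#'
#' `load_catalog()` after `write_catalog()` reproduces the catalog exactly
#' (canonical serialisation round trip).
#'
#' @param catalog a `deg_catalog`.
#' @param path,registry_path output files.
#' @export
write_catalog <- function(catalog, path, registry_path) {
  stopifnot(inherits(catalog, "deg_catalog"))
  reg <- catalog$registry
  reg$is_outgroup <- as.integer(reg$is_outgroup)
  reg$is_reference_anchor <- as.integer(reg$is_reference_anchor)
  write_tsv(as.data.frame(reg)[REGISTRY_COLS], registry_path)
  rec <- catalog$records
  rec$not_family <- as.integer(rec$not_family)
  rec$active <- ifelse(is.na(rec$active), "", as.character(as.integer(rec$active)))
  write_tsv(rec[CATALOG_COLS], path)
  invisible(c(path, registry_path))
}

#' @export
print.deg_catalog <- function(x, ...) {
  cat("Protein family catalog:", nrow(x$records), "records,",
      nrow(x$registry), "species\n")
  tab <- table(x$records$species)
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  if (any(x$records$not_family))
    cat("  flagged as probable non-family:", sum(x$records$not_family), "\n")
  invisible(x)
}

#' Read amino-acid sequences from FASTA
#'
#' Sequences are upper-cased; stop characters (`*`) are stripped with a
#' warning; characters outside the 20-residue alphabet plus X raise an
#' error.  The id of each record is the first whitespace-delimited token of
#' its header.
#'
#' @param path FASTA file (plain text, single-line or wrapped).
#' @return named character vector, id -> sequence.
#' @export
load_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripping '*' stop characters from ",
            sum(grepl("*", seqs, fixed = TRUE)), " sequence(s)")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  ok <- grepl(paste0("^[", paste(AA_ALPHABET21, collapse = ""), "]*$"), seqs)
  if (!all(ok))
    stop("sequence '", ids[!ok][1L],
         "' contains characters outside the amino-acid alphabet + X")
  seqs
}

#' Write amino-acid sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width for wrapping (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(names(seqs) != ""))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s))
      writeLines(substring(s, seq(1L, nchar(s), width),
                           pmin(seq(1L, nchar(s), width) + width - 1L,
                                nchar(s))), con)
  }
  invisible(path)
}

#' Cross-validate a catalog against a sequence set
#'
#' Reports ids present in only one of the two sources and disagreements
#' between the catalog's `length_aa` and the actual sequence length.  An
#' empty report means the sources are consistent.
#'
#' @param catalog a `deg_catalog`.
#' @param sequences named character vector as from [load_fasta()].
#' @return data frame with columns `id`, `type`
#'   (`missing_sequence` / `orphan_sequence` / `length_mismatch`), `detail`.
#' @export
cross_validate <- function(catalog, sequences) {
  stopifnot(inherits(catalog, "deg_catalog"))
  rec <- catalog$records
  out <- list()
  miss <- setdiff(rec$id, names(sequences))
  if (length(miss))
    out[[length(out) + 1L]] <- data.frame(id = miss, type = "missing_sequence",
                                          detail = "in catalog only")
  orph <- setdiff(names(sequences), rec$id)
  if (length(orph))
    out[[length(out) + 1L]] <- data.frame(id = orph, type = "orphan_sequence",
                                          detail = "in FASTA only")
  both <- intersect(rec$id, names(sequences))
  if (length(both)) {
    la <- rec$length_aa[match(both, rec$id)]
    ls <- nchar(sequences[both])
    bad <- both[la != ls]
    if (length(bad))
      out[[length(out) + 1L]] <- data.frame(
        id = bad, type = "length_mismatch",
        detail = paste0("catalog ", la[match(bad, both)],
                        " aa vs sequence ", ls[match(bad, both)], " aa"))
  }
  if (!length(out))
    return(data.frame(id = character(), type = character(),
                      detail = character()))
  do.call(rbind, out)
}

#' Path to a bundled example/fixture file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @export
degphylo_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "degphylo")))
  p <- system.file("extdata", file, package = "degphylo")
  if (p == "") stop("no bundled file named ", file)
  p
}

# -- shared TSV helpers -------------------------------------------------------

read_tsv_checked <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  d <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                  check.names = FALSE, quote = "", comment.char = "")
  missing <- setdiff(cols, names(d))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  d[cols]
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
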