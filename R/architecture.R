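# Domain architectures: the N- to C-terminal ordered list of domain tokens
# of a protein.  The token set is closed over PD (trypsin-type protease
# domain), PD_ia (degenerated/proteolytically inactive protease domain),
# PDZ (protein-interaction domain) and NT (N-terminal extension); any other
# token is carried through verbatim as an "other" domain label (e.g. the
# beta-glycanhydrolase fusion seen in one green-alga family member, which
# is represented, not judged).

DOMAIN_TOKENS <- c("PD", "PD_ia", "PDZ", "NT")

#' Parse a domain-arrangement string
#'
#' Tokens are separated by `-`; whitespace and the trailing-underscore
#' spelling variants of `PD_ia` are normalised.  Unknown tokens are kept as
#' free "other" labels.
#'
#' @param text architecture string, e.g. `"PD-PDZ-PDZ-PD_ia-PDZ-PDZ"`.
#' @return character vector of tokens with class `deg_architecture`.
#' @examples
#' parse_architecture("NT-PD")
#' parse_architecture("PD-PDZ-PDZ- PD_ia_-PDZ-PDZ")   # spacing variant
#' @export
parse_architecture <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty architecture string")
  toks <- trimws(strsplit(text, "-", fixed = TRUE)[[1L]])
  toks <- toks[nzchar(toks)]
  # PD_ia split by its own separator-free variants: normalise "PD_ia_",
  # "PDia", "PD_IA" etc.
  toks <- vapply(toks, function(t) {
    tn <- sub("_+$", "", t)
    if (toupper(gsub("_", "", tn)) == "PDIA") return("PD_ia")
    if (toupper(tn) %in% DOMAIN_TOKENS) return(toupper(tn))
    if (tn == "PDZ") return("PDZ")
    tn
  }, "")
  if (!length(toks)) stop("empty architecture string")
  structure(unname(toks), class = "deg_architecture")
}

#' @export
format.deg_architecture <- function(x, ...) paste(unclass(x), collapse = "-")

#' @export
print.deg_architecture <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Count domains of a given kind in an architecture
#'
#' @param a a `deg_architecture` (or string, parsed on the fly).
#' @param kind domain token, e.g. `"PDZ"`.
#' @return integer count.
#' @examples
#' count_domains(parse_architecture("PD-PDZ-PDZ-PD_ia-PDZ-PDZ"), "PDZ")  # 4
#' @export
count_domains <- function(a, kind) {
  if (is.character(a) && !inherits(a, "deg_architecture"))
    a <- parse_architecture(a)
  sum(unclass(a) == kind)
}

is_other_domain <- function(token) !(token %in% DOMAIN_TOKENS)
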