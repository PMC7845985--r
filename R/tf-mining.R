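# Keyword mining of functional descriptions into the 13 drought-associated
# transcription-factor families. Matching is annotation-text based (the
# descriptions come from BLAST-style homology annotation), case-insensitive,
# with more specific patterns tried first so e.g. a dehydration-responsive
# element binding (DREB) description is not swallowed by the generic AP2
# rule, and "N-MYC downregulated" lands in MYC rather than nowhere.

# ordered rule list; first match wins
TF_RULES <- list(
  DREB = "\\bdreb\\b|dehydration[- ]responsive element",
  ERD  = "\\berd\\b|early[- ]respons\\w* to dehydration",
  ERF  = "\\berf\\b|ethylene respons\\w* factor",
  AP2  = "\\bap2\\b|\\bap2\\.",
  HSF  = "\\bhsf\\b|heat shock (transcription )?factor",
  NFY  = "\\bnf-?y\\b|nuclear factor y",
  MYC  = "\\bmyc\\b",
  MYB  = "\\bmyb\\b",
  NAC  = "\\bnac\\b",
  WRKY = "wrky",
  bZIP = "bzip",
  bHLH = "bhlh|helix-loop-helix",
  C2H2 = "c2h2|zinc finger"
)

#' Classify a functional description into a TF family
#'
#' Case-insensitive keyword matching against an ordered rule list covering
#' the 13 drought-associated families (DREB, bZIP, HSF, MYC, MYB, NAC, AP2,
#' NFY, ERF, WRKY, C2H2, bHLH, ERD); the first matching rule wins and a
#' description matching no rule maps to NA. Classification is deterministic
#' and total.
#'
#' @param description character vector of free-text functional descriptions
#'   (non-empty).
#' @return character vector: a family name or NA per description.
#' @examples
#' classify_tf("WRKY DNA-binding protein 27")   # "WRKY"
#' classify_tf("40S ribosomal protein")         # NA
#' @export
classify_tf <- function(description) {
  if (any(is.na(description)) || any(!nzchar(description)))
    stop("descriptions must be non-empty text")
  out <- rep(NA_character_, length(description))
  todo <- rep(TRUE, length(description))
  for (fam in names(TF_RULES)) {
    hit <- todo & grepl(TF_RULES[[fam]], description,
                        ignore.case = TRUE, perl = TRUE)
    out[hit] <- fam
    todo <- todo & !hit
  }
  out
}

#' Annotate a gene table with TF families
#'
#' @param annotations data.frame with columns gene_id and description.
#' @return the same data.frame with a tf_family column added.
#' @export
annotate_tf <- function(annotations) {
  annotations$tf_family <- classify_tf(annotations$description)
  annotations
}

#' Per-family TF counts
#'
#' Tallies annotated records per family over the closed 13-family vocabulary;
#' the total equals the number of records with a non-missing family.
#'
#' @param annotations data.frame with a tf_family column (NA = not a TF).
#' @return list with \code{counts} (named integer vector over all 13
#'   families) and \code{total}.
#' @export
family_counts <- function(annotations) {
  fam <- annotations$tf_family
  bad <- !is.na(fam) & !fam %in% TF_FAMILIES
  if (any(bad))
    stop("unknown TF family label(s): ",
         paste(unique(fam[bad]), collapse = ", "))
  counts <- stats::setNames(integer(length(TF_FAMILIES)), TF_FAMILIES)
  tab <- table(fam[!is.na(fam)])
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, total = sum(counts))
}
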