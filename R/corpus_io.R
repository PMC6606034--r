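# Data model and readers/writers for the three corpus tables:
#   findings(claim_id, drug, gene, direction, paper_id, stance)
#   papers(paper_id, authors, methods, references, journal_score)
#   signatures(drug, gene, cell_line, dose, duration, z)
# Set-valued paper fields are semicolon-joined tokens on disk and parsed to
# character vectors in memory (list columns).

FINDINGS_COLS   <- c("claim_id", "drug", "gene", "direction", "paper_id", "stance")
PAPERS_COLS     <- c("paper_id", "authors", "methods", "references", "journal_score")
SIGNATURES_COLS <- c("drug", "gene", "cell_line", "dose", "duration", "z")

read_table_auto <- function(path) {
  # sniff delimiter from the header line: tab wins over comma
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE,
             colClasses = "character", check.names = FALSE)
}

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s table: missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read a claim corpus from findings, paper-metadata and signature tables
#'
#' The three tables may be tab- or comma-separated (sniffed from the header
#' line) and must carry the documented columns. Referential integrity is
#' enforced: every finding must reference a known paper, every claim keeps at
#' least one finding, and `(paper_id, claim_id)` pairs are unique.
#'
#' @param findings_path path to the findings table
#'   (`claim_id, drug, gene, direction, paper_id, stance`).
#' @param papers_path path to the paper metadata table
#'   (`paper_id, authors, methods, references, journal_score`); the three
#'   set-valued columns are semicolon-joined token lists.
#' @param signatures_path path to the long signature table
#'   (`drug, gene, cell_line, dose, duration, z`).
#' @return a `claim_corpus`: list with `claims` (one row per claim),
#'   `findings`, `papers` (authors/methods/references as list columns) and
#'   `signatures` data frames.
#' @export
read_corpus <- function(findings_path, papers_path, signatures_path) {
  for (p in c(findings_path, papers_path, signatures_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  findings <- check_schema(read_table_auto(findings_path), FINDINGS_COLS, "findings")
  papers_raw <- check_schema(read_table_auto(papers_path), PAPERS_COLS, "papers")
  signatures <- check_schema(read_table_auto(signatures_path), SIGNATURES_COLS, "signatures")
  signatures$z <- as.numeric(signatures$z)
  papers <- data.frame(paper_id = papers_raw$paper_id, stringsAsFactors = FALSE)
  papers$authors    <- lapply(papers_raw$authors, split_tokens)
  papers$methods    <- lapply(papers_raw$methods, split_tokens)
  papers$references <- lapply(papers_raw$references, split_tokens)
  papers$journal_score <- as.numeric(papers_raw$journal_score)
  new_corpus(findings, papers, signatures)
}

# Assemble and validate a claim_corpus from in-memory tables.
new_corpus <- function(findings, papers, signatures) {
  stopifnot(is.data.frame(findings), is.data.frame(papers), is.data.frame(signatures))
  if (nrow(findings)) {
    bad_dir <- setdiff(unique(findings$direction), c("increase", "decrease"))
    if (length(bad_dir)) {
      stop("findings: unknown direction value(s): ", paste(bad_dir, collapse = ", "),
           call. = FALSE)
    }
    bad_stance <- setdiff(unique(findings$stance), c("support", "oppose"))
    if (length(bad_stance)) {
      stop("findings: unknown stance value(s): ", paste(bad_stance, collapse = ", "),
           call. = FALSE)
    }
    dangling <- setdiff(unique(findings$paper_id), papers$paper_id)
    if (length(dangling)) {
      stop("integrity error: finding(s) reference unknown paper_id(s): ",
           paste(sort(dangling), collapse = ", "), call. = FALSE)
    }
    dup <- duplicated(findings[, c("paper_id", "claim_id")])
    if (any(dup)) {
      stop("integrity error: duplicated (paper_id, claim_id) pair(s): ",
           paste(unique(paste(findings$paper_id[dup], findings$claim_id[dup],
                              sep = "/")), collapse = ", "), call. = FALSE)
    }
    # one (drug, gene, direction) triple per claim_id
    u <- unique(findings[, c("claim_id", "drug", "gene", "direction")])
    if (anyDuplicated(u$claim_id)) {
      offenders <- unique(u$claim_id[duplicated(u$claim_id)])
      stop("integrity error: claim_id(s) mapped to multiple (drug, gene, direction) ",
           "triples: ", paste(offenders, collapse = ", "), call. = FALSE)
    }
    claims <- u
  } else {
    claims <- data.frame(claim_id = character(0), drug = character(0),
                         gene = character(0), direction = character(0),
                         stringsAsFactors = FALSE)
  }
  if (!all(signatures_finite <- is.finite(signatures$z))) {
    stop("signatures: non-finite z at row(s) ",
         paste(which(!signatures_finite), collapse = ", "), call. = FALSE)
  }
  empty_auth <- lengths(papers$authors) == 0
  if (any(empty_auth)) {
    stop("papers: empty author set for paper_id(s): ",
         paste(papers$paper_id[empty_auth], collapse = ", "), call. = FALSE)
  }
  structure(list(claims = claims, findings = findings, papers = papers,
                 signatures = signatures),
            class = "claim_corpus")
}

#' @export
print.claim_corpus <- function(x, ...) {
  cat("claim_corpus:", nrow(x$claims), "claims,", nrow(x$findings), "findings,",
      nrow(x$papers), "papers,", nrow(x$signatures), "signature z-scores\n")
  invisible(x)
}

#' Write a claim corpus to the three on-disk tables
#'
#' Inverse of [read_corpus()]: writes tab-separated tables with headers;
#' list-valued paper fields are re-joined with semicolons.
#'
#' @param corpus a `claim_corpus`.
#' @param findings_path,papers_path,signatures_path output paths.
#' @return the paths, invisibly.
#' @export
write_corpus <- function(corpus, findings_path, papers_path, signatures_path) {
  stopifnot(inherits(corpus, "claim_corpus"))
  wt <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(corpus$findings, findings_path)
  p <- corpus$papers
  pf <- data.frame(paper_id = p$paper_id,
                   authors = vapply(p$authors, join_tokens, ""),
                   methods = vapply(p$methods, join_tokens, ""),
                   references = vapply(p$references, join_tokens, ""),
                   journal_score = p$journal_score,
                   stringsAsFactors = FALSE)
  wt(pf, papers_path)
  wt(corpus$signatures, signatures_path)
  invisible(c(findings_path, papers_path, signatures_path))
}

#' Restrict a corpus to claims with experimental signatures
#'
#' Keeps only claims whose `(drug, gene)` key — matched case-insensitively
#' after stripping whitespace — has at least one signature z-score, mirroring
#' the intersection of literature-curated interactions with the
#' high-throughput experiment. An empty intersection is valid.
#'
#' @param corpus a `claim_corpus`.
#' @return the filtered `claim_corpus`, with a `summary` attribute recording
#'   the number of matched claims and of supporting / opposing findings.
#' @export
match_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "claim_corpus"))
  sig_keys <- unique(dgi_key(corpus$signatures$drug, corpus$signatures$gene))
  keep <- dgi_key(corpus$claims$drug, corpus$claims$gene) %in% sig_keys
  claims <- corpus$claims[keep, , drop = FALSE]
  findings <- corpus$findings[corpus$findings$claim_id %in% claims$claim_id, , drop = FALSE]
  papers <- corpus$papers[corpus$papers$paper_id %in% findings$paper_id, , drop = FALSE]
  out <- structure(list(claims = claims, findings = findings, papers = papers,
                        signatures = corpus$signatures),
                   class = "claim_corpus")
  gt <- attr(corpus, "ground_truth")
  if (!is.null(gt)) {
    attr(out, "ground_truth") <- gt[gt$claim_id %in% claims$claim_id, , drop = FALSE]
  }
  attr(out, "summary") <- list(
    n_claims = nrow(claims),
    n_supporting = sum(findings$stance == "support"),
    n_opposing = sum(findings$stance == "oppose"))
  out
}

#' Signature z-scores for one claim key
#'
#' @param corpus a `claim_corpus`.
#' @param drug,gene claim key (normalized before matching).
#' @return numeric vector of moderated z-scores (possibly empty).
#' @export
signature_z <- function(corpus, drug, gene) {
  s <- corpus$signatures
  s$z[dgi_key(s$drug, s$gene) == dgi_key(drug, gene)]
}
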