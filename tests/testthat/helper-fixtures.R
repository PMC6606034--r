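# Fixture builders: corpora are constructed in code, written to temp files
# and re-read through the public I/O layer.

write_fixture_tables <- function(findings, papers, signatures, dir = tempfile("corpus")) {
  dir.create(dir)
  paths <- file.path(dir, c("findings.tsv", "papers.tsv", "signatures.tsv"))
  write.table(findings, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(papers, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(signatures, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

read_fixture <- function(findings, papers, signatures) {
  paths <- write_fixture_tables(findings, papers, signatures)
  on.exit(unlink(dirname(paths[1]), recursive = TRUE))
  read_corpus(paths[1], paths[2], paths[3])
}

# three claims, four papers, two signature keys
tiny_findings <- function() {
  data.frame(
    claim_id = c("c1", "c1", "c2", "c3"),
    drug = c("aspirin", "aspirin", "aspirin", "ibuprofen"),
    gene = c("TP53", "TP53", "EGFR", "TP53"),
    direction = c("increase", "increase", "decrease", "increase"),
    paper_id = c("p1", "p2", "p3", "p4"),
    stance = c("support", "oppose", "support", "support"),
    stringsAsFactors = FALSE)
}

tiny_papers <- function() {
  data.frame(
    paper_id = c("p1", "p2", "p3", "p4"),
    authors = c("a1;a2", "a2;a3", "a4", "a5"),
    methods = c("m1;m2", "m2", "m3", "m1"),
    references = c("r1;r2;r3", "r3", "r4", "r5"),
    journal_score = c(1.2, 0.4, 2.0, 0.1),
    stringsAsFactors = FALSE)
}

tiny_signatures <- function() {
  data.frame(
    drug = rep(c("aspirin", "aspirin"), each = 3),
    gene = rep(c("TP53", "EGFR"), each = 3),
    cell_line = rep(c("CL1", "CL2", "CL3"), 2),
    dose = "d1", duration = "t1",
    z = c(1.5, 2.0, 2.5, -0.5, -1.0, 0.3),
    stringsAsFactors = FALSE)
}

tiny_corpus <- function() {
  read_fixture(tiny_findings(), tiny_papers(), tiny_signatures())
}

# corpus of two-paper claims realizing exact pair counts:
# n_ov pairs with a shared author (a_ov agreeing) and n_in disjoint-author
# pairs (a_in agreeing). Each claim contributes exactly one paper pair.
pair_count_corpus <- function(n_ov, a_ov, n_in, a_in) {
  n <- n_ov + n_in
  claim <- sprintf("c%05d", seq_len(n))
  agree <- c(rep(c(TRUE, FALSE), c(a_ov, n_ov - a_ov)),
             rep(c(TRUE, FALSE), c(a_in, n_in - a_in)))
  shared <- rep(c(TRUE, FALSE), c(n_ov, n_in))
  p1 <- sprintf("p%05da", seq_len(n))
  p2 <- sprintf("p%05db", seq_len(n))
  findings <- data.frame(
    claim_id = rep(claim, each = 2),
    drug = rep(sprintf("d%05d", seq_len(n)), each = 2),
    gene = rep(sprintf("g%05d", seq_len(n)), each = 2),
    direction = "increase",
    paper_id = as.vector(rbind(p1, p2)),
    stance = as.vector(rbind("support", ifelse(agree, "support", "oppose"))),
    stringsAsFactors = FALSE)
  papers <- data.frame(
    paper_id = c(p1, p2),
    authors = c(sprintf("au%05dx", seq_len(n)),
                ifelse(shared, sprintf("au%05dx", seq_len(n)),
                       sprintf("au%05dy", seq_len(n)))),
    methods = "m1", references = "r1", journal_score = 1,
    stringsAsFactors = FALSE)
  signatures <- data.frame(drug = "d00001", gene = "g00001", cell_line = "CL1",
                           dose = "d1", duration = "t1", z = 1,
                           stringsAsFactors = FALSE)
  read_fixture(findings, papers, signatures)
}
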