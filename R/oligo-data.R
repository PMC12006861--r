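#' Characterized PQS oligonucleotides from p53 target promoters
#'
#' The panel of promoter-derived oligonucleotides whose G-quadruplex
#' propensity was characterized alongside the genome-wide analysis: the
#' putative G4-forming sequence near each p53 target gene, the reported
#' distance between the p53 response element and the PQS (`"overlap"` when
#' they share bases), and the reported whole-sequence G4Hunter score. Note
#' that four entries (PCNA, PIDD1, ASTN2, PURPL) carry reported scores that
#' do not equal the mean per-base run score of the printed sequence under
#' any consistent normalization; [g4hunter_score()] reproduces the
#' remaining nine exactly.
#'
#' @return Data frame with columns `name`, `sequence`, `re_pqs_distance`
#'   (character: bp or `"overlap"`), `reported_score`, and
#'   `score_consistent` (whether the reported score equals the
#'   mean-per-base score of the printed sequence).
#' @export
g4_oligos <- function() {
  df <- data.frame(
    name = c("PCNA", "GDF15", "BBC3-01", "BBC3-02", "PIDD1", "INPP5B",
             "ASTN2", "TRIM32", "PURPL", "RPS19-01", "RPS19-02", "CXCR2",
             "MDM2"),
    sequence = c(
      "CGGGTTCAGGAGTCAAAGAGGCGGGGA",
      "AGGGAGGGGTGGGTGAGGC",
      "ACTTGTCCGCGGCGGGCGGGCGGGG",
      "CGGGGCGGGGCGGGGCGGGGC",
      "TGGGCGATGGCTGCAACGGTGGAGGGGC",
      "GTGGCGCAGGGGCTGTTGGGAAATG",
      "CGGGGCAAGGCGGCCCTGCAGGGGTGA",
      "TGGGGAGGCGGGGCTCAGTGACGGACAGGGA",
      "TGGGGCAAGTGGGTGGAGCCATGAGGA",
      "TGGGCCCCGGGGGGCAGCGGCGGGGT",
      "CGGGGGGCAGCGGCGGGGTGCGTGGGGCGTCCGGA",
      "AGTCCGTTGGCGGGGGCTGGGATG",
      "GGGCGGGATTGGGCCGGTTCAGTGGG"),
    re_pqs_distance = c("8", "8", "overlap", "10", "21", "17", "22",
                        "overlap", "30", "26", "32", "overlap", "30"),
    reported_score = c(1.240, 2.000, 1.240, 2.810, 1.346, 1.200, 1.160,
                       1.484, 1.240, 1.346, 1.657, 1.250, 1.346),
    stringsAsFactors = FALSE)
  df$score_consistent <- vapply(seq_len(nrow(df)), function(i) {
    isTRUE(all.equal(round(g4hunter_score(df$sequence[i]), 3),
                     df$reported_score[i], tolerance = 5e-4))
  }, logical(1))
  df
}

#' Response-element and PQS constructs of the yeast reporter strains
#'
#' The insert sequences cloned upstream of the minimal promoter in the
#' luciferase reporter strains: RE-only constructs (`BBC3_RE`, `MDM2_RE`)
#' and the native RE+PQS arrangements (`BBC3`, `MDM2`).
#'
#' @return Data frame with columns `strain` and `sequence`.
#' @export
re_constructs <- function() {
  data.frame(
    strain = c("BBC3_RE", "BBC3", "MDM2_RE", "MDM2"),
    sequence = c(
      "CTGCAAGTCCTGACTTGTCC",
      "CTGCAAGTCCTGACTTGTCCGCGGCGGGCGGGCGGGG",
      "GGTCAAGTTCAGACACGTTC",
      "GGGCGGGATTGGGCCGGTTCAGTGGGCAGGTTGACTCAGCTTTTCCTCTTGAGCTGGTCAAGTTCAGACACGTTC"),
    stringsAsFactors = FALSE)
}
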