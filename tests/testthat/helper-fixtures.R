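# Published substitution-class cross-tabulations for the two transporter
# subunits (rows = wild-type class, columns = mutant class, order
# hydrophobic / polar / positive / negative).

table_b0at_counts <- function() {
  matrix(c(20, 10, 12, 3,
           5,  0,  1,  1,
           2,  1,  1,  1,
           0,  0,  0,  1),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("HYDROPHOBIC", "POLAR", "POSITIVE", "NEGATIVE"),
                         c("HYDROPHOBIC", "POLAR", "POSITIVE", "NEGATIVE")))
}

table_rbat_counts <- function() {
  matrix(c(17, 15, 13, 4,
           10,  2,  6, 2,
           10,  5,  2, 0,
           3,   1,  4, 0),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("HYDROPHOBIC", "POLAR", "POSITIVE", "NEGATIVE"),
                         c("HYDROPHOBIC", "POLAR", "POSITIVE", "NEGATIVE")))
}

# Engineer a missense mutation list whose cross-tab reproduces given cell
# counts, using one representative residue pair per (wild-type, mutant)
# class pair.
mutations_from_counts <- function(counts) {
  wt_rep <- c(HYDROPHOBIC = "Leu", POLAR = "Ser", POSITIVE = "Arg",
              NEGATIVE = "Asp")
  mut_rep <- c(HYDROPHOBIC = "Ile", POLAR = "Thr", POSITIVE = "Lys",
               NEGATIVE = "Glu")
  hgvs <- character()
  pos <- 1L
  for (i in rownames(counts)) {
    for (j in colnames(counts)) {
      k <- counts[i, j]
      if (k > 0) {
        hgvs <- c(hgvs, paste0("p.", wt_rep[[i]], pos - 1L + seq_len(k),
                               mut_rep[[j]]))
        pos <- pos + k
      }
    }
  }
  parse_hgvs_p(hgvs)
}

# Independent full-enumeration oracle for the exact two-sided rank-sum p:
# enumerate every assignment of the pooled mid-ranks to sample 1.
bf_ranksum_p <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x)
  r <- rank(z)
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (length(z) + 1) / 2
  subs <- utils::combn(length(z), n1)
  ws <- apply(subs, 2, function(s) sum(r[s]))
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

# Independent oracle for tie-free inputs built on R's null Wilcoxon
# distribution (dwilcox works on U = W1 - n1(n1+1)/2).
dwilcox_two_sided_p <- function(w_obs, n1, n2) {
  u <- 0:(n1 * n2)
  pw <- stats::dwilcox(u, n1, n2)
  W <- u + n1 * (n1 + 1) / 2
  mu <- n1 * (n1 + n2 + 1) / 2
  sum(pw[abs(W - mu) >= abs(w_obs - mu) - 1e-9])
}

# Small two-patient dominant cohort whose single mutations carry the given
# PolyPhen2 scores; used by the threshold-scan tests.
two_patient_polyphen_fixture <- function(scores = c(0.3, 0.9)) {
  variants <- tibble::tibble(
    gene = "SLC7A9", hgvs_p = c("p.Ala10Val", "p.Gly20Arg"),
    consequence = "MISSENSE", allele_frequency = 0, consurf = 5L, ddg = -1,
    sift = 0.5, polyphen2 = scores, mutation_assessor = 1, fathmm = 0,
    condel = 0.5, cadd = 10, disease_associated = TRUE)
  patients <- tibble::tibble(
    patient_id = c("P1", "P2"), gene = "SLC7A9",
    allele1_mutations = c("p.Ala10Val", "p.Gly20Arg"),
    allele2_mutations = "")
  list(variants = variants, patients = patients)
}

quiet_score_cohort <- function(...) {
  suppressMessages(suppressWarnings(score_cohort(...)))
}
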