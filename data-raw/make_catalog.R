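# One-off generator for inst/extdata fixtures: synthetic signature catalog
# and gene lists. Deterministic, no RNG.

bases <- c("A", "C", "G", "T")
subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
chans <- unlist(lapply(subs, function(s) {
  as.vector(t(outer(bases, bases, function(p5, p3) paste0(p5, "[", s, "]", p3))))
}))
p5 <- substr(chans, 1, 1)
p3 <- substr(chans, 7, 7)
sub_of <- rep(subs, each = 16)

blockw <- function(w) w[match(sub_of, subs)]

# tobacco: C>A dominated, 5' C/T preference
w_tob <- blockw(c(0.65, 0.10, 0.15, 0.05, 0.04, 0.01)) *
  (1 + 0.8 * (p5 %in% c("C", "T"))) * (1 + 0.4 * (p3 %in% c("A", "C")))

# clock: C>T at NpCpG
w_clk <- ifelse(sub_of == "C>T" & p3 == "G", 1, 0) * 0.85 / 4 +
  ifelse(sub_of == "C>T" & p3 != "G", 1, 0) * 0.15 / 12

# apobec: TpC context C>T and C>G
w_apo <- ifelse(sub_of == "C>T" & p5 == "T", 0.50 / 4, 0) +
  ifelse(sub_of == "C>G" & p5 == "T", 0.45 / 4, 0) +
  ifelse(sub_of %in% c("C>A") & p5 != "T", 0.05 / 12, 0)

# hrd: broad with mild structured tilt
w_hrd <- blockw(c(0.10, 0.12, 0.16, 0.18, 0.27, 0.17)) *
  (1 + 0.35 * sin(seq_along(chans) / 5))

# pol-eta: T>A / T>C with 5' A/T preference
w_pol <- blockw(c(0.03, 0.02, 0.05, 0.42, 0.36, 0.12)) *
  ifelse(sub_of %in% c("T>A", "T>C", "T>G"), 1 + 1.2 * (p5 %in% c("A", "T")), 1)

w_bg <- rep(1, 96)

mat <- rbind(tobacco = w_tob, clock = w_clk, apobec = w_apo,
             hrd = w_hrd, poleta = w_pol, background = w_bg)
mat <- mat / rowSums(mat)
stopifnot(qr(mat)$rank == 6)

out <- data.frame(signature = rownames(mat), mat, check.names = FALSE)
colnames(out) <- c("signature", chans)
readr::write_tsv(out, "inst/extdata/signature_catalog_synthetic.tsv")

drivers <- c(
  "# Recurrent lung and pan-cancer driver genes (compact default list)",
  "TP53", "KRAS", "EGFR", "FAT1", "PTEN", "RB1", "CDKN2A", "MYC", "CCND3",
  "FGFR1", "TP63", "SETD2", "ARID1A", "NOTCH2", "SMARCA4", "STK11", "KEAP1",
  "NF1", "BRAF", "PIK3CA", "TSC1", "WT1", "ERBB3", "RHEB", "SOS1", "SOS2",
  "EZH2", "JAK2", "ERBB4", "ATM")
writeLines(drivers, "inst/extdata/driver_genes.tsv")

repair <- c(
  "# DNA-repair genes implicated in repair of tobacco-induced damage",
  "ERCC1", "ERCC5", "ERCC8", "LIG4", "MUTYH", "NEIL1", "NEIL3", "POLB",
  "RECQL4", "REV1", "REV3L", "TDG", "MBD4", "RPA1", "FANCA", "FANCL",
  "RAD50", "RAD51B", "CHEK1", "ATM", "ATR", "BRCA2")
writeLines(repair, "inst/extdata/repair_genes.tsv")

cat("written\n")
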