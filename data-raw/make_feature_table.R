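# Builds inst/extdata/aa_features.tsv: the default 20 x 36 per-residue feature
# table (5 atomic-composition counts + 31 AAindex physicochemical scales).
# Run from the package root: Rscript data-raw/make_feature_table.R
suppressMessages(library(seqinr))
data(aaindex)

aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

# Atom counts of the free amino acids (C, H, N, O, S), from molecular formulas.
formulas <- list(
  A = c(3, 7, 1, 2, 0),  R = c(6, 14, 4, 2, 0), N = c(4, 8, 2, 3, 0),
  D = c(4, 7, 1, 4, 0),  C = c(3, 7, 1, 2, 1),  Q = c(5, 10, 2, 3, 0),
  E = c(5, 9, 1, 4, 0),  G = c(2, 5, 1, 2, 0),  H = c(6, 9, 3, 2, 0),
  I = c(6, 13, 1, 2, 0), L = c(6, 13, 1, 2, 0), K = c(6, 14, 2, 2, 0),
  M = c(5, 11, 1, 2, 1), F = c(9, 11, 1, 2, 0), P = c(5, 9, 1, 2, 0),
  S = c(3, 7, 1, 3, 0),  T = c(4, 9, 1, 3, 0),  W = c(11, 12, 2, 2, 0),
  Y = c(9, 11, 1, 3, 0), V = c(5, 11, 1, 2, 0))
atoms <- do.call(rbind, formulas)
colnames(atoms) <- c("n_carbon", "n_hydrogen", "n_nitrogen", "n_oxygen", "n_sulfur")

# 31 AAindex entries covering hydrophobicity, volume/size, polarity, charge,
# secondary-structure propensity, flexibility and burial.
scales <- c(
  KYTJ820101 = "hydropathy_kd",        HOPT810101 = "hydrophilicity_hw",
  EISD840101 = "hydrophobicity_eisenberg", ZIMJ680101 = "hydrophobicity_zimmerman",
  JOND750101 = "hydrophobicity_jones", PONP800101 = "surrounding_hydrophobicity",
  NOZY710101 = "transfer_energy_nozaki", WOLR810101 = "hydration_potential",
  FASG760101 = "molecular_weight",     BIGC670101 = "residue_volume",
  GRAR740103 = "volume_grantham",      DAWD720101 = "size_dawson",
  FAUJ880103 = "vdw_volume_normalized", CHOC760101 = "asa_tripeptide",
  JANJ780101 = "asa_folded",           JANJ780102 = "percent_buried",
  ROSG850101 = "mean_buried_area",     GRAR740102 = "polarity_grantham",
  ZIMJ680103 = "polarity_zimmerman",   ZIMJ680104 = "isoelectric_point",
  KLEP840101 = "net_charge",           FAUJ880109 = "h_bond_donors",
  CHAM820101 = "polarizability",       MCMT640101 = "refractivity",
  CHOP780201 = "helix_propensity_cf",  CHOP780202 = "sheet_propensity_cf",
  CHOP780203 = "turn_propensity_cf",   BHAR880101 = "flexibility_bhaskaran",
  LEVM760101 = "hydrophobic_param_levitt", CHAM810101 = "steric_parameter",
  OOBM770101 = "ave_nonbonded_energy")

acc <- vapply(aaindex, function(x) x$H, character(1))
scale_mat <- sapply(names(scales), function(a) {
  v <- aaindex[[which(acc == a)]]$I
  stopifnot(!anyNA(v))
  unname(v[aa3[rownames(atoms)]])
})
colnames(scale_mat) <- unname(scales)

tab <- data.frame(residue = rownames(atoms), atoms, scale_mat,
                  check.names = FALSE, stringsAsFactors = FALSE)
stopifnot(nrow(tab) == 20, ncol(tab) == 37)
write.table(tab, "inst/extdata/aa_features.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote inst/extdata/aa_features.tsv:", nrow(tab), "x", ncol(tab) - 1, "\n")
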