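# Physicochemical partitions used by the CTD descriptor family.
#
# Thirteen attributes, each splitting the 20 standard amino acids into three
# disjoint groups (the classic Dubchak-style tables as distributed with the
# iFeature toolkit: seven hydrophobicity scales, normalized van der Waals
# volume, polarity, polarizability, charge, secondary structure, solvent
# accessibility). 13 properties x 3 groups gives the 39/39/195 dimensions of
# CTDC/CTDT/CTDD. Every triple is a partition of the alphabet; tests assert
# this.

CTD_PROPERTIES <- list(
  hydrophobicity_PRAM900101 = c(g1 = "RKEDQN",     g2 = "GASTPHY",          g3 = "CLVIMFW"),
  hydrophobicity_ARGP820101 = c(g1 = "QSTNGDE",    g2 = "RAHCKMV",          g3 = "LYPFIW"),
  hydrophobicity_ZIMJ680101 = c(g1 = "QNGSWTDERA", g2 = "HMCKV",            g3 = "LPFYI"),
  hydrophobicity_PONP930101 = c(g1 = "KPDESNQT",   g2 = "GRHA",             g3 = "YMFWLCVI"),
  hydrophobicity_CASG920101 = c(g1 = "KDEQPSRNTG", g2 = "AHYMLV",           g3 = "FIWC"),
  hydrophobicity_ENGD860101 = c(g1 = "RDKENQHYP",  g2 = "SGTAW",            g3 = "CVLIMF"),
  hydrophobicity_FASG890101 = c(g1 = "KERSQD",     g2 = "NTPG",             g3 = "AYHWVMFLIC"),
  normwaalsvolume           = c(g1 = "GASTPDC",    g2 = "NVEQIL",           g3 = "MHKFRYW"),
  polarity                  = c(g1 = "LIFWCMVY",   g2 = "PATGS",            g3 = "HQRKNED"),
  polarizability            = c(g1 = "GASDT",      g2 = "CPNVEQIL",         g3 = "KMHFRYW"),
  charge                    = c(g1 = "KR",         g2 = "ANCQGHILMFPSTWYV", g3 = "DE"),
  secondarystruct           = c(g1 = "EALMQKRH",   g2 = "VIYCWFT",          g3 = "GNPSD"),
  solventaccess             = c(g1 = "ALFCGIVW",   g2 = "RKQEND",           g3 = "MSPTHY")
)

# Five-group physicochemical scheme for GAAC/GDPC.
GAAC_GROUPS <- list(
  aliphatic = c("G", "A", "V", "L", "M", "I"),
  aromatic  = c("F", "Y", "W"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  uncharged = c("S", "T", "C", "P", "N", "Q")
)

# residue -> group-index lookup for one CTD property
ctd_group_index <- function(property) {
  groups <- CTD_PROPERTIES[[property]]
  idx <- integer(0)
  for (g in 1:3) {
    letters_g <- seq_chars(groups[[g]])
    idx[letters_g] <- g
  }
  idx[AA_ALPHABET]
}
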