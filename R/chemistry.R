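# Residue/atom-name dictionaries for hydrogen-bond and salt-bridge chemistry.
#
# Conventions: backbone N is a donor heavy atom (except PRO), backbone O and
# terminal OXT are acceptors; side-chain lists cover the polar atoms of the
# standard residues.  Histidine follows the neutral NE2-protonated (HIE)
# tautomer: ND1 accepts, NE2 donates.  Acid oxygens are the carboxylates
# (ASP OD1/OD2, GLU OE1/OE2, OXT); base nitrogens the LYS/ARG/HIS side-chain
# nitrogens.  The TOY pseudo-residue of the synthetic generator has no
# donor/acceptor chemistry by default.

SIDECHAIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2", HIS = "NE2", TRP = "NE1",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2")
)

SIDECHAIN_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "OD1", GLN = "OE1", HIS = "ND1", MET = "SD",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

ACID_OXYGENS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

BASE_NITROGENS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                       HIS = c("ND1", "NE2"))

in_dict <- function(dict, resname, name) {
  hit <- dict[resname]
  mapply(function(names_allowed, nm) !is.null(names_allowed) &&
           nm %in% names_allowed,
         hit, name, USE.NAMES = FALSE)
}

chem_flags <- function(atoms) {
  resname <- atoms$resname
  name <- atoms$name
  donor <- (name == "N" & resname != "PRO") |
    in_dict(SIDECHAIN_DONORS, resname, name)
  acceptor <- name %in% c("O", "OXT") |
    in_dict(SIDECHAIN_ACCEPTORS, resname, name)
  acid <- name == "OXT" | in_dict(ACID_OXYGENS, resname, name)
  base <- in_dict(BASE_NITROGENS, resname, name)
  list(is_donor_heavy = donor, is_acceptor = acceptor,
       is_acid_oxygen = acid, is_base_nitrogen = base)
}
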