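# Physical constants (CODATA 2018). Internal length unit is nm throughout;
# masses in amu; energies in kJ/mol; entropy in J mol^-1 K^-1.

.const <- list(
  kB      = 1.380649e-23,       # Boltzmann, J K^-1
  hbar    = 1.054571817e-34,    # reduced Planck, J s
  Rgas    = 8.314462618,        # gas constant, J mol^-1 K^-1
  amu     = 1.66053906660e-27,  # atomic mass unit, kg
  nm2_m2  = 1e-18,              # nm^2 -> m^2
  # Coulomb constant e^2/(4 pi eps0) in kJ mol^-1 nm e^-2
  kc_kJmol_nm = 138.935458
)

# Atomic masses (amu) for the elements that occur in protein/water systems.
.element_masses <- c(
  "H" = 1.008, "C" = 12.011, "N" = 14.007, "O" = 15.999, "S" = 32.06,
  "P" = 30.974, "SE" = 78.971, "NA" = 22.990, "CL" = 35.45, "K" = 39.098,
  "MG" = 24.305, "CA" = 40.078, "ZN" = 65.38, "FE" = 55.845, "MN" = 54.938
)

.mass_for_element <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- 12.011  # unknown elements get a carbon-like placeholder
  unname(m)
}

# Standard 3-letter residue codes treated as protein.
.protein_resnames <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "HSD", "HSE", "HSP", "HIE", "HID", "HIP"
)

# Water residue names recognised by the `water` selection keyword.
.water_resnames <- c("HOH", "WAT", "SOL", "TIP", "TIP3", "SPC")
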