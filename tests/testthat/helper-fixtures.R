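# Shared fixture builders (all programmatic; nothing on disk).

# small rigid toy complex for fast unit tests
toy2 <- function(n = 10, seed = 7, flex = integer(0), noise = 0.1) {
  make_toy_complex(synth_config(n_residues = n, flex_span = flex,
                                noise_sd = noise, seed = seed), id = "TOY")
}

# hand-built structure from an atom spec matrix: chain, resno, elety, x, y, z
manual_structure <- function(df, id = "MAN", partners = list(p1 = "A", p2 = "B")) {
  df$icode <- ""
  df$resid <- "ALA"
  df$element <- substr(df$elety, 1, 1)
  df$b <- 10
  df$occ <- 1
  new_complex_structure(id, df, partners)
}

# fixed-column PDB ATOM line
pdb_line <- function(serial, name, alt, resid, chain, resno, x, y, z,
                     occ = 1, b = 10, element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resid, chain, resno, x, y, z, occ, b, element)
}
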