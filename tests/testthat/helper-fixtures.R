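# Shared fixtures: everything is generated in code, nothing is stored.

default_scheme <- scoring_scheme()

# Reduced-length reference panel: keeps genome-scale tests fast while
# exercising the same code paths as the realistic default lengths.
tiny_lengths <- function() {
  c(pgsB = 60, pgsC = 40, pgsA = 58, ywtC = 35, pgdS = 62,
    racE = 50, ggt = 70, pghB = 45, pghC = 47, pghL = 46, pghZ = 48)
}

tiny_panel <- function(seed = 7) generate_reference_panel(seed, tiny_lengths())

random_peptide <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# a minimal hand-written GenBank text with one forward and one complement CDS
fixture_genbank_text <- function() {
  c(
    "LOCUS       FIX001            1000 bp    DNA     linear   BCT 01-JAN-2024",
    "DEFINITION  coordinate-convention fixture.",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    "     CDS             join(101..400)",
    "                     /locus_tag=\"FIX_0001\"",
    "                     /gene=\"pgsB\"",
    "                     /translation=\"MKKLVVLLAGHN\"",
    "     CDS             complement(501..800)",
    "                     /locus_tag=\"FIX_0002\"",
    "                     /gene=\"pgsC\"",
    "                     /translation=\"MDEWAAGHKLVV\"",
    "//"
  )
}

write_fixture_genbank <- function(path = tempfile(fileext = ".gbk")) {
  writeLines(fixture_genbank_text(), path)
  path
}

# reference with known residues at fixed positions for notation tests
notation_reference <- function() {
  paste0(strrep("A", 73), "D", strrep("G", 26))  # D at position 74, length 100
}
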