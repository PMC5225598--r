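test_that("read_structure parses chains and classifies polymers", {
  path <- mini_protein_pdb()
  chains <- read_structure(path)
  expect_length(chains, 1)
  ch <- chains[["A"]]
  expect_s3_class(ch, "ChainStructure")
  expect_equal(nrow(ch$residues), 3)
  expect_equal(ch$polymer_class, "protein")
  expect_equal(ch$residues$aa1, c("A", "G", "L"))
  expect_false(any(is.na(ch$residues$ca_x)))

  # a ribonucleotide in the same file is classified rna, chain flagged mixed
  path2 <- write_mini_pdb(c(
    pdb_line(1, " CA ", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, " CA ", "GLY", "A", 2, 4, 0, 0),
    pdb_line(3, " P  ", "U  ", "A", 3, 8, 0, 0, elem = "P"),
    pdb_line(4, " C1'", "U  ", "A", 3, 9, 1, 0, elem = "C")
  ))
  ch2 <- read_structure(path2)[["A"]]
  expect_equal(ch2$residues$polymer_class, c("protein", "protein", "rna"))
  expect_equal(ch2$polymer_class, "mixed")

  # waters excluded entirely
  path3 <- write_mini_pdb(c(
    pdb_line(1, " O  ", "HOH", "A", 1, 0, 0, 0, record = "HETATM",
             elem = "O"),
    pdb_line(2, " O  ", "HOH", "A", 2, 3, 0, 0, record = "HETATM",
             elem = "O")
  ))
  expect_length(read_structure(path3), 0)
})

test_that("mmCIF input yields the same chain structures as PDB", {
  cif <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_test", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    "ATOM 1 C CA . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 4.000 0.000 0.000 1.00 0.00 ? 2 GLY A CA 1",
    "ATOM 3 C CA . LEU A 1 3 ? 8.000 1.000 0.000 1.00 0.00 ? 3 LEU A CA 1"
  ), cif)
  ch <- read_structure(cif, format = "mmcif")[["A"]]
  expect_equal(ch$residues$aa1, c("A", "G", "L"))
  expect_equal(ch$polymer_class, "protein")
  expect_equal(ch$residues$ca_x, c(0, 4, 8))
})

test_that("parsing is deterministic and missing files error", {
  path <- mini_protein_pdb()
  expect_identical(read_structure(path), read_structure(path))
  expect_error(read_structure(tempfile()), "not found")
})

test_that("alternate locations keep the highest-occupancy conformer", {
  l1 <- pdb_line(1, " CA ", "ALA", "A", 1, 0, 0, 0)
  l2 <- pdb_line(2, " CA ", "ALA", "A", 1, 9, 9, 9)
  substr(l1, 17, 17) <- "A"; substr(l1, 55, 60) <- "  0.30"
  substr(l2, 17, 17) <- "B"; substr(l2, 55, 60) <- "  0.70"
  ch <- read_structure(write_mini_pdb(c(
    l1, l2, pdb_line(3, " CA ", "GLY", "A", 2, 4, 0, 0))))[["A"]]
  expect_equal(nrow(ch$residues), 2)
  expect_equal(ch$residues$ca_x[1], 9)  # the 0.70-occupancy B conformer
})

test_that("pocket TSV dialect round-trips and validates", {
  defs <- list(
    structure(list(pocket_id = "1ABC:1:A",
                   members = data.frame(chain_id = "A", seq_num = c(5L, 9L, 12L, 20L, 33L),
                                        icode = c("", "", "A", "", ""),
                                        stringsAsFactors = FALSE)),
              class = "PocketDefinition"),
    structure(list(pocket_id = "1ABC:2:B",
                   members = data.frame(chain_id = "B", seq_num = c(7L, 8L, 100L),
                                        icode = "", stringsAsFactors = FALSE)),
              class = "PocketDefinition"))
  names(defs) <- c("1ABC:1:A", "1ABC:2:B")
  path <- tempfile(fileext = ".tsv")
  write_pocket_definitions(defs, path)
  back <- read_pocket_definitions(path, dialect = "tsv")
  expect_equal(back, defs)
  expect_equal(vapply(back, function(d) nrow(d$members), integer(1)),
               c("1ABC:1:A" = 5L, "1ABC:2:B" = 3L))

  # duplicate residue row cites both line numbers
  lines <- readLines(path)
  writeLines(c(lines, lines[2]), path)
  expect_error(read_pocket_definitions(path), "lines 2 and 10")

  # malformed row cites its line
  writeLines(c(lines[1], "1ABC:1:A\tA\tnotanumber\t-"), path)
  expect_error(read_pocket_definitions(path), "line 2")
})

test_that("castp .poc fixture parses with synthesized pocket ids", {
  poc <- system.file("extdata", "example.poc", package = "pocketmotif")
  defs <- read_pocket_definitions(poc, dialect = "castp_poc",
                                  structure_id = "1XYZ")
  expect_named(defs, c("1XYZ:1:A", "1XYZ:2:B"))
  expect_equal(nrow(defs[["1XYZ:1:A"]]$members), 4)  # one residue has 2 atoms
  expect_equal(nrow(defs[["1XYZ:2:B"]]$members), 3)
})

test_that("resolve_pocket extracts CA coordinates or reports offenders", {
  path <- mini_protein_pdb()
  chains <- read_structure(path)
  defn <- structure(list(pocket_id = "P:1:A",
                         members = data.frame(chain_id = "A",
                                              seq_num = 1:3, icode = "",
                                              stringsAsFactors = FALSE)),
                    class = "PocketDefinition")
  p <- resolve_pocket(defn, chains)
  expect_s3_class(p, "PocketStructure")
  expect_equal(nrow(p$xyz), nrow(defn$members))
  expect_equal(p$aa, c("A", "G", "L"))
  expect_false(any(p$binding))

  defn$members$seq_num <- c(1L, 2L, 99L)
  expect_error(resolve_pocket(defn, chains), "A/99")

  # residue present but no CA atom
  path2 <- write_mini_pdb(c(
    pdb_line(1, " CA ", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, " N  ", "GLY", "A", 2, 4, 0, 0, elem = "N"),
    pdb_line(3, " CA ", "LEU", "A", 3, 8, 0, 0)
  ))
  defn$members$seq_num <- 1:3
  expect_error(resolve_pocket(defn, read_structure(path2)), "no CA")
})
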