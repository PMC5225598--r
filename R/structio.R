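# Coordinate / pocket-definition IO and pocket resolution.
# PDB and mmCIF parsing is delegated to bio3d; the pocket TSV dialect and the
# CASTp .poc reader are defined here.

# Modified residues mapped to their parent amino acid; anything else that
# bio3d cannot translate becomes 'X' (alignable, excluded from motif
# frequencies).
.MOD_AA <- c(
  MSE = "M", SEC = "C", PYL = "K", CSO = "C", CME = "C", OCS = "C",
  PTR = "Y", SEP = "S", TPO = "T", HYP = "P", MLY = "K", M3L = "K",
  KCX = "K", FME = "M", CSX = "C", LLP = "K", PCA = "Q"
)

.STD_AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
              "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

# Ribonucleotides: the four standard bases, inosine and common modifications.
.RNA_RES <- c("A","C","G","U","I","N","PSU","H2U","1MA","2MG","M2G","5MC",
              "5MU","7MG","OMC","OMG","4SU","MIA","1MG","YG","YYG","T6A",
              "G7M","A2M","UR3","4OC","MA6")

.WATER_RES <- c("HOH","DOD","WAT","H2O","SOL")

.classify_residue <- function(resid) {
  resid <- toupper(trimws(resid))
  ifelse(resid %in% c(.STD_AA3, names(.MOD_AA)), "protein",
         ifelse(resid %in% .RNA_RES, "rna", "other"))
}

.aa_one <- function(resid) {
  resid <- toupper(trimws(resid))
  out <- unname(.MOD_AA[resid])
  std <- bio3d::aa321(resid)
  out[is.na(out)] <- std[is.na(out)]
  out[is.na(out) | !out %in% LETTERS] <- "X"
  out
}

# Keep the highest-occupancy alternate conformer per atom; ties broken by
# altloc letter order.
.filter_altloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt %in% c("", "A"))) return(atom)
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  atom <- atom[ord, , drop = FALSE]
  atom[!duplicated(key[ord]), , drop = FALSE]
}

#' Read a coordinate file into per-chain structures
#'
#' Parses a PDB or mmCIF file (via bio3d), drops waters, keeps the
#' highest-occupancy alternate conformer, and classifies every residue as
#' protein, RNA or other from its residue name (standard amino acids and a
#' built-in modified-residue table count as protein; A/C/G/U/I and common
#' modified ribonucleotides as RNA).
#'
#' @param path path to the coordinate file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (from the file extension).
#' @return A named list of `ChainStructure` objects (one per chain, named by
#'   chain id). Each holds the atom table, a residue table with CA
#'   coordinates, and a `polymer_class` that is either uniform or `"mixed"`.
#'   Chains left empty after water removal are dropped; a water-only file
#'   yields an empty list.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") suppressWarnings(bio3d::read.cif(path,
                                                            verbose = FALSE))
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  atom <- parsed$atom
  if (is.null(atom) || nrow(atom) == 0)
    stop("empty structure: no atom records in ", path)
  atom <- atom[!toupper(atom$resid) %in% .WATER_RES, , drop = FALSE]
  if (nrow(atom) == 0) return(structure(list(), names = character()))
  atom <- .filter_altloc(atom)
  atom$insert[is.na(atom$insert)] <- ""
  atom$chain[is.na(atom$chain)] <- " "
  sid <- sub("\\.(pdb|ent|cif)$", "", basename(path), ignore.case = TRUE)

  out <- list()
  for (ch in sort(unique(atom$chain))) {
    at <- atom[atom$chain == ch, , drop = FALSE]
    rkey <- paste(at$resno, at$insert, sep = "\r")
    first <- !duplicated(rkey)
    res <- data.frame(
      chain_id = ch,
      seq_num = at$resno[first],
      icode = at$insert[first],
      name3 = toupper(trimws(at$resid[first])),
      stringsAsFactors = FALSE
    )
    res$polymer_class <- .classify_residue(res$name3)
    res$aa1 <- NA_character_
    is_aa <- res$polymer_class == "protein"
    if (any(is_aa)) res$aa1[is_aa] <- .aa_one(res$name3[is_aa])
    # CA alpha-carbons only: require the residue to be an amino acid so that
    # calcium ions (resid CA, elety CA) are never picked up
    atom_class <- res$polymer_class[match(rkey, rkey[first])]
    is_ca <- trimws(at$elety) == "CA" & atom_class == "protein"
    ca_rows <- which(is_ca)[match(rkey[first], rkey[is_ca])]
    res$ca_x <- at$x[ca_rows]
    res$ca_y <- at$y[ca_rows]
    res$ca_z <- at$z[ca_rows]
    cls <- unique(res$polymer_class)
    out[[ch]] <- structure(
      list(structure_id = sid, chain_id = ch, atoms = at, residues = res,
           polymer_class = if (length(cls) == 1) cls else "mixed"),
      class = "ChainStructure"
    )
  }
  out
}

#' @export
print.ChainStructure <- function(x, ...) {
  cat(sprintf("ChainStructure %s:%s — %d residues (%s), %d atoms\n",
              x$structure_id, x$chain_id, nrow(x$residues), x$polymer_class,
              nrow(x$atoms)))
  invisible(x)
}

#' Read pocket definitions
#'
#' Two dialects are supported.
#'
#' * `tsv`: tab-separated with header `pocket_id  chain_id  seq_num  icode`,
#'   one residue per row, `-` for an empty insertion code, `#` comment lines.
#' * `castp_poc`: a CASTp-style `.poc` file. CASTp output dialects vary; the
#'   variant read here is whitespace-separated ATOM records whose final field
#'   is the pocket number (see `inst/extdata/example.poc`). Pocket ids are
#'   synthesized as `protein_ID:pocket_ID:chain_ID`.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"castp_poc"`.
#' @param structure_id protein id used when synthesizing pocket ids for the
#'   `.poc` dialect (default: file basename).
#' @return Named list of `PocketDefinition` objects: `pocket_id` plus a
#'   `members` data frame (`chain_id`, `seq_num`, `icode`).
#' @export
read_pocket_definitions <- function(path, dialect = c("tsv", "castp_poc"),
                                    structure_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") .read_pockets_tsv(path) else
    .read_pockets_poc(path, structure_id)
}

.read_pockets_tsv <- function(path) {
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0) stop("no data rows in ", path)
  header <- strsplit(raw[keep[1]], "\t", fixed = TRUE)[[1]]
  want <- c("pocket_id", "chain_id", "seq_num", "icode")
  if (!identical(header, want))
    stop("bad TSV header in ", path, ": expected ", paste(want, collapse = "\t"))
  rows <- keep[-1]
  recs <- lapply(seq_along(rows), function(i) {
    f <- strsplit(raw[rows[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4 || is.na(suppressWarnings(as.integer(f[3]))))
      stop("malformed pocket row at line ", rows[i], " of ", path)
    data.frame(pocket_id = f[1], chain_id = f[2],
               seq_num = as.integer(f[3]),
               icode = if (f[4] == "-") "" else f[4],
               line = rows[i], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, recs)
  key <- paste(tab$pocket_id, tab$chain_id, tab$seq_num, tab$icode, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate pocket residue entry at lines ",
         paste(tab$line[key == d], collapse = " and "), " of ", path)
  }
  .defs_from_table(tab)
}

.read_pockets_poc <- function(path, structure_id) {
  if (is.null(structure_id))
    structure_id <- sub("\\.poc$", "", basename(path), ignore.case = TRUE)
  raw <- readLines(path)
  rows <- which(grepl("^(ATOM|HETATM)", raw))
  if (length(rows) == 0) stop("no ATOM records in .poc file ", path)
  recs <- lapply(rows, function(i) {
    f <- strsplit(trimws(raw[i]), "\\s+")[[1]]
    pid <- suppressWarnings(as.integer(f[length(f)]))
    resno <- suppressWarnings(as.integer(f[6]))
    if (is.na(pid) || is.na(resno) || length(f) < 7)
      stop("malformed .poc record at line ", i, " of ", path)
    data.frame(poc = pid, chain_id = f[5], seq_num = resno, icode = "",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, recs)
  tab <- unique(tab)
  tab$pocket_id <- sprintf("%s:%d:%s", structure_id, tab$poc, tab$chain_id)
  .defs_from_table(tab[, c("pocket_id", "chain_id", "seq_num", "icode")])
}

.defs_from_table <- function(tab) {
  ids <- unique(tab$pocket_id)
  defs <- lapply(ids, function(id) {
    m <- tab[tab$pocket_id == id, c("chain_id", "seq_num", "icode")]
    rownames(m) <- NULL
    structure(list(pocket_id = id, members = m), class = "PocketDefinition")
  })
  names(defs) <- ids
  defs
}

#' Write pocket definitions in the package TSV dialect
#'
#' Inverse of [read_pocket_definitions()] for the `tsv` dialect.
#'
#' @param defs named list of `PocketDefinition`.
#' @param path output file.
#' @export
write_pocket_definitions <- function(defs, path) {
  rows <- lapply(defs, function(d) {
    data.frame(pocket_id = d$pocket_id, chain_id = d$members$chain_id,
               seq_num = d$members$seq_num,
               icode = ifelse(d$members$icode == "", "-", d$members$icode),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("pocket_id\tchain_id\tseq_num\ticode", con)
  writeLines(sprintf("%s\t%s\t%d\t%s", tab$pocket_id, tab$chain_id,
                     tab$seq_num, tab$icode), con)
  invisible(path)
}

#' Resolve a pocket definition against parsed chains
#'
#' Looks up every member residue in the parsed chains and extracts its CA
#' coordinate and one-letter code. Residues are matched on author numbering
#' (chain id, residue number, insertion code) exactly; mismatches are
#' reported, never guessed.
#'
#' @param defn a `PocketDefinition`.
#' @param chains named list of `ChainStructure` from [read_structure()].
#' @return A `PocketStructure`: `pocket_id`, `keys` data frame, `aa`
#'   one-letter codes, `xyz` n x 3 CA coordinate matrix (Angstrom),
#'   `binding` logical flags (initialized `FALSE`), `source_pos` residue
#'   numbers.
#' @export
resolve_pocket <- function(defn, chains) {
  stopifnot(inherits(defn, "PocketDefinition"))
  m <- defn$members
  n <- nrow(m)
  aa <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  bad <- character(0)
  for (i in seq_len(n)) {
    ch <- chains[[m$chain_id[i]]]
    if (is.null(ch)) {
      bad <- c(bad, sprintf("%s/%d%s (chain missing)", m$chain_id[i],
                            m$seq_num[i], m$icode[i]))
      next
    }
    r <- ch$residues
    hit <- which(r$seq_num == m$seq_num[i] & r$icode == m$icode[i])
    if (length(hit) == 0) {
      bad <- c(bad, sprintf("%s/%d%s (residue missing)", m$chain_id[i],
                            m$seq_num[i], m$icode[i]))
      next
    }
    hit <- hit[1]
    if (is.na(r$ca_x[hit])) {
      bad <- c(bad, sprintf("%s/%d%s (no CA atom)", m$chain_id[i],
                            m$seq_num[i], m$icode[i]))
      next
    }
    aa[i] <- if (is.na(r$aa1[hit])) "X" else r$aa1[hit]
    xyz[i, ] <- c(r$ca_x[hit], r$ca_y[hit], r$ca_z[hit])
  }
  if (length(bad) > 0)
    stop("cannot resolve pocket ", defn$pocket_id, ": ",
         paste(bad, collapse = ", "))
  new_pocket(defn$pocket_id, xyz, aa, keys = m, source_pos = m$seq_num)
}

#' Construct a PocketStructure
#'
#' Low-level constructor used by [resolve_pocket()] and the synthetic
#' generators.
#'
#' @param pocket_id identifier, conventionally `protein:pocket:chain`.
#' @param xyz n x 3 matrix of CA coordinates (Angstrom).
#' @param aa one-letter residue codes (`"X"` for unknown).
#' @param keys optional data frame (`chain_id`, `seq_num`, `icode`).
#' @param binding logical RNA-binding flags per residue.
#' @param source_pos source sequence positions.
#' @export
new_pocket <- function(pocket_id, xyz, aa,
                       keys = NULL, binding = NULL, source_pos = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(n >= 1, ncol(xyz) == 3, all(is.finite(xyz)), length(aa) == n)
  if (is.null(keys))
    keys <- data.frame(chain_id = "A", seq_num = seq_len(n), icode = "",
                       stringsAsFactors = FALSE)
  if (is.null(binding)) binding <- rep(FALSE, n)
  if (is.null(source_pos)) source_pos <- keys$seq_num
  structure(list(pocket_id = pocket_id, keys = keys, aa = aa,
                 xyz = unname(xyz), binding = binding,
                 source_pos = as.integer(source_pos)),
            class = "PocketStructure")
}

#' @export
print.PocketStructure <- function(x, ...) {
  cat(sprintf("PocketStructure %s — %d residues (%d RNA-binding): %s\n",
              x$pocket_id, nrow(x$xyz), sum(x$binding),
              paste(x$aa, collapse = "")))
  invisible(x)
}

# Shared table writer: tab-separated, one header line, 6 significant digits.
.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
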