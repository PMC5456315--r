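## Structures are stored as an S3 object: a label plus an ordered atom
## table.  The atom table is the common currency of every later stage
## (charging, mutation, Poisson-Boltzmann, skins).

#' Construct a Structure object
#'
#' A `Structure` is a label plus an ordered data frame of atoms with one
#' row per atom and columns `serial`, `name`, `element`, `res_name`,
#' `res_seq`, `chain`, `x`, `y`, `z`, `charge`, `radius`, `het`.
#' Atoms are expected to be grouped contiguously by `(chain, res_seq)`,
#' in file order.  Author residue numbering is preserved throughout.
#'
#' @param atoms data frame of atoms (see Details).
#' @param id character label for the structure.
#' @return An object of class `"Structure"`.
#' @export
new_structure <- function(atoms, id = "structure") {
  required <- c("serial", "name", "element", "res_name", "res_seq",
                "chain", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  if (is.null(atoms$het)) atoms$het <- FALSE
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) > 0 && !all(is.finite(coords))) {
    stop("non-finite atom coordinates")
  }
  if (any(!is.na(atoms$radius) & atoms$radius < 0)) {
    stop("negative atom radius")
  }
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  nres <- nrow(unique(a[, c("chain", "res_seq")]))
  cat(sprintf("Structure '%s': %d atoms, %d residues, %d chain(s)\n",
              x$id, nrow(a), nres, length(unique(a$chain))))
  if (any(a$charge != 0)) {
    cat(sprintf("  net charge: %+.2f e\n", sum(a$charge)))
  }
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `Structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Atom coordinates as a matrix
#' @param s a `Structure`.
#' @return numeric matrix with one row per atom, columns x, y, z.
#' @export
coords <- function(s) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

guess_element <- function(name) {
  stripped <- gsub("[0-9' ]", "", name)
  two <- toupper(substr(stripped, 1, 2))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
         two, toupper(substr(stripped, 1, 1)))
}

parse_pdb_lines <- function(lines, include_het = FALSE) {
  ## first model only: stop at the first ENDMDL
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]
  sel <- grep("^(ATOM  |HETATM)", lines)
  if (length(sel) == 0) stop("no ATOM records in PDB input")
  recs <- lines[sel]
  num <- function(txt, line_no) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) & nzchar(trimws(txt)))
    if (length(bad) > 0 || anyNA(v)) {
      bad1 <- if (length(bad) > 0) bad[1] else which(is.na(v))[1]
      stop(sprintf("cannot parse numeric field at line %d: '%s'",
                   line_no[bad1], txt[bad1]))
    }
    v
  }
  f <- function(a, b) substr(recs, a, b)
  atoms <- data.frame(
    serial   = as.integer(num(f(7, 11), sel)),
    name     = trimws(f(13, 16)),
    altloc   = f(17, 17),
    res_name = trimws(f(18, 20)),
    chain    = f(22, 22),
    res_seq  = as.integer(num(f(23, 26), sel)),
    x        = num(f(31, 38), sel),
    y        = num(f(39, 46), sel),
    z        = num(f(47, 54), sel),
    occ      = suppressWarnings(as.numeric(f(55, 60))),
    element  = trimws(f(77, 78)),
    het      = startsWith(recs, "HETATM"),
    stringsAsFactors = FALSE
  )
  atoms$occ[is.na(atoms$occ)] <- 1
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- guess_element(atoms$name[blank])
  if (!include_het) {
    atoms <- atoms[!atoms$het & atoms$res_name != "HOH", , drop = FALSE]
  } else {
    atoms <- atoms[atoms$res_name != "HOH", , drop = FALSE]
  }
  if (nrow(atoms) == 0) stop("no ATOM records (only HETATM/water)")
  ## alternate locations: keep highest occupancy, ties to lowest altloc letter
  if (any(nzchar(trimws(atoms$altloc)))) {
    key <- paste(atoms$chain, atoms$res_seq, atoms$name, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
      if (length(idx) == 1) return(idx)
      sub <- atoms[idx, ]
      ord <- order(-sub$occ, sub$altloc)
      idx[ord[1]]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  atoms$charge <- 0
  atoms$radius <- NA_real_
  atoms[, c("serial", "name", "element", "res_name", "res_seq", "chain",
            "x", "y", "z", "charge", "radius", "het")]
}

parse_pqr_lines <- function(lines, include_het = FALSE) {
  sel <- grep("^(ATOM|HETATM)", lines)
  if (length(sel) == 0) stop("no ATOM records in PQR input")
  rows <- lapply(sel, function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    ## with chain: rec serial name res chain resseq x y z q r  (11 tokens)
    ## without:    rec serial name res resseq x y z q r        (10 tokens)
    if (length(tok) == 11) {
      chain <- tok[5]; rest <- tok[6:11]
    } else if (length(tok) == 10) {
      chain <- " "; rest <- tok[5:10]
    } else {
      stop(sprintf("malformed PQR record at line %d (%d fields)",
                   i, length(tok)))
    }
    vals <- suppressWarnings(as.numeric(rest))
    if (anyNA(vals)) stop(sprintf("cannot parse PQR numerics at line %d", i))
    data.frame(serial = as.integer(tok[2]), name = tok[3],
               res_name = tok[4], chain = chain,
               res_seq = as.integer(vals[1]),
               x = vals[2], y = vals[3], z = vals[4],
               charge = vals[5], radius = vals[6],
               het = startsWith(lines[i], "HETATM"),
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  if (!include_het) {
    atoms <- atoms[!atoms$het & atoms$res_name != "HOH", , drop = FALSE]
  }
  if (nrow(atoms) == 0) stop("no ATOM records (only HETATM/water)")
  atoms$element <- guess_element(atoms$name)
  atoms[, c("serial", "name", "element", "res_name", "res_seq", "chain",
            "x", "y", "z", "charge", "radius", "het")]
}

#' Read a protein structure from PDB or PQR
#'
#' PDB files are parsed by fixed columns (coordinates to 0.001 A); PQR
#' files by whitespace, populating per-atom partial charge and radius.
#' For multi-model PDB files the first model is used; alternate
#' locations are resolved to the highest occupancy (ties: lowest altloc
#' letter).  HETATM records and waters are excluded unless
#' `include_het = TRUE`.
#'
#' @param source path to a file, or a character vector of record lines.
#' @param format `"auto"` (by file extension, default), `"pdb"` or `"pqr"`.
#' @param include_het keep HETATM records (waters are always dropped).
#' @param id label for the structure; defaults to the file name.
#' @return a [new_structure()] object.
#' @export
read_structure <- function(source, format = c("auto", "pdb", "pqr"),
                           include_het = FALSE, id = NULL) {
  format <- match.arg(format)
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|pqr|ent)$", "", basename(source))
    if (format == "auto") {
      format <- if (grepl("\\.pqr$", source, ignore.case = TRUE)) "pqr" else "pdb"
    }
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    if (is.null(id)) id <- "structure"
    if (format == "auto") {
      stop("format must be given explicitly ('pdb' or 'pqr') for text input")
    }
  }
  atoms <- switch(format,
    pdb = parse_pdb_lines(lines, include_het),
    pqr = parse_pqr_lines(lines, include_het)
  )
  new_structure(atoms, id = id)
}

#' Write a structure to PDB or PQR
#'
#' @param s a `Structure`.
#' @param path output file path.
#' @param format `"pdb"` or `"pqr"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "pqr")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  }
  a <- s$atoms
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  if (format == "pdb") {
    ## PDB atom-name column convention: names of < 4 characters start in
    ## column 14 when the element symbol is a single character
    nm <- ifelse(nchar(a$name) >= 4 | nchar(a$element) >= 2,
                 sprintf("%-4s", a$name), sprintf(" %-3s", a$name))
    lines <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, a$serial %% 100000L, nm, a$res_name,
                     substr(paste0(a$chain, " "), 1, 1), a$res_seq,
                     a$x, a$y, a$z, 1, 0, a$element)
  } else {
    if (anyNA(a$radius)) {
      stop("cannot write PQR: radii not assigned (see assign_charges)")
    }
    lines <- sprintf("%s %5d %-4s %-3s %1s %4d %11.4f %11.4f %11.4f %8.4f %7.4f",
                     trimws(rec), a$serial %% 100000L, a$name, a$res_name,
                     substr(paste0(a$chain, " "), 1, 1), a$res_seq,
                     a$x, a$y, a$z, a$charge, a$radius)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Per-chain amino-acid sequence of a structure
#'
#' One letter per residue possessing at least one backbone atom
#' (N, CA or C); non-standard residues become `"X"`.
#'
#' @param s a `Structure`.
#' @param chain optional chain identifier; default: all chains.
#' @return named character vector of one-letter sequences, one per chain.
#' @export
structure_sequence <- function(s, chain = NULL) {
  a <- s$atoms[!s$atoms$het, , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms in selection")
  a <- a[a$name %in% c("N", "CA", "C"), , drop = FALSE]
  out <- vapply(split(a, a$chain), function(ch) {
    res <- ch[!duplicated(ch$res_seq), , drop = FALSE]
    res <- res[order(match(res$res_seq, ch$res_seq)), , drop = FALSE]
    paste(aa3_to_1(res$res_name), collapse = "")
  }, character(1))
  out
}

#' Residue table of a structure
#'
#' @param s a `Structure`.
#' @return data frame with one row per residue: `chain`, `res_seq`,
#'   `res_name`, `n_atoms`.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$res_seq, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], res_seq = a$res_seq[first],
             res_name = a$res_name[first],
             n_atoms = as.vector(table(factor(key, levels = key[first]))),
             stringsAsFactors = FALSE)
}

#' Classify residues as basic / acidic / neutral
#'
#' Basic residues are His, Lys and Arg (the surface class highlighted in
#' comparative renderings of methyltransferase surfaces); acidic are Asp
#' and Glu; everything else is neutral.  The three classes partition the
#' residues.
#'
#' @param s a `Structure`.
#' @return named integer vector with counts `basic`, `acidic`, `neutral`
#'   and `total`.
#' @export
residue_class_summary <- function(s) {
  rt <- residue_table(s)
  basic <- sum(rt$res_name %in% c("HIS", "LYS", "ARG"))
  acidic <- sum(rt$res_name %in% c("ASP", "GLU"))
  c(basic = basic, acidic = acidic,
    neutral = nrow(rt) - basic - acidic, total = nrow(rt))
}
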