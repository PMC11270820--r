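#' Read trajectory frames from disk
#'
#' Supports the extended XYZ dialect (a `Lattice="..."` / `Properties=...`
#' comment line) and LAMMPS text dumps (`ITEM: ATOMS` with column
#' auto-detection of `id`, `mol`, `type`/`element`, and `x y z` or scaled
#' `xs ys zs` coordinates). Fractional coordinates are converted to
#' Cartesian Angstrom at read time.
#'
#' @param path path to a trajectory file.
#' @param format `"auto"` (sniffed from content), `"extxyz"` or
#'   `"lammps_dump"`.
#' @return a list of [simulation_frame()] objects, in file order.
#' @export
read_frames <- function(path, format = c("auto", "extxyz", "lammps_dump")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (length(lines) && grepl("^ITEM:", lines[[1]]))
      "lammps_dump" else "extxyz"
  }
  switch(format,
         extxyz = read_extxyz_lines(lines),
         lammps_dump = read_lammps_lines(lines))
}

parse_error <- function(lineno, msg) {
  stop("parse error at line ", lineno, ": ", msg, call. = FALSE)
}

split_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

## --- extended XYZ ---------------------------------------------------------

parse_extxyz_comment <- function(comment) {
  ## key=value pairs, values possibly quoted
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("([^"]*)"|[^ ]+)'
  m <- gregexpr(pat, comment, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    kv <- substr(comment, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", kv, fixed = TRUE)
    key <- substr(kv, 1L, eq - 1L)
    val <- substr(kv, eq + 1L, nchar(kv))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

read_extxyz_lines <- function(lines) {
  frames <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[[i]]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[[i]])))
    if (is.na(nat) || nat < 1L)
      parse_error(i, "expected atom count")
    if (i + 1L + nat > length(lines))
      parse_error(i, "truncated frame: fewer atom records than declared")
    hdr <- parse_extxyz_comment(lines[[i + 1L]])
    cell <- NULL; pbc <- c(FALSE, FALSE, FALSE)
    if (!is.null(hdr$Lattice)) {
      v <- as.numeric(split_fields(hdr$Lattice))
      if (length(v) != 9L || anyNA(v))
        parse_error(i + 1L, "Lattice field must hold 9 numbers")
      cell <- matrix(v, nrow = 3L, byrow = TRUE)
      pbc <- c(TRUE, TRUE, TRUE)
    }
    if (!is.null(hdr$pbc)) {
      p <- toupper(split_fields(hdr$pbc))
      if (length(p) == 3L) pbc <- p %in% c("T", "TRUE", "1")
    }
    props <- if (!is.null(hdr$Properties)) hdr$Properties else
      "species:S:1:pos:R:3"
    pf <- strsplit(props, ":")[[1]]
    if (length(pf) %% 3L != 0L)
      parse_error(i + 1L, "malformed Properties field")
    pnames <- pf[seq(1L, length(pf), 3L)]
    pcols <- as.integer(pf[seq(3L, length(pf), 3L)])
    col_of <- function(name) {
      k <- match(name, pnames)
      if (is.na(k)) return(NA_integer_)
      if (k == 1L) 1L else sum(pcols[seq_len(k - 1L)]) + 1L
    }
    sp_col <- col_of("species"); pos_col <- col_of("pos")
    mol_col <- col_of("mol")
    if (is.na(sp_col) || is.na(pos_col))
      parse_error(i + 1L, "Properties must include species and pos")
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "[ \t]+")
    ncols <- sum(pcols)
    pos <- matrix(NA_real_, nat, 3L)
    types <- character(nat)
    mols <- if (!is.na(mol_col)) integer(nat) else NULL
    for (a in seq_len(nat)) {
      tk <- toks[[a]]
      if (length(tk) < ncols)
        parse_error(i + 1L + a, "too few columns in atom record")
      types[a] <- tk[sp_col]
      xyz <- suppressWarnings(as.numeric(tk[pos_col:(pos_col + 2L)]))
      if (anyNA(xyz)) parse_error(i + 1L + a, "non-numeric coordinate")
      pos[a, ] <- xyz
      if (!is.null(mols)) mols[a] <- as.integer(tk[mol_col])
    }
    check_elements(types, paste0("frame ", fidx))
    time <- if (!is.null(hdr$Time)) as.numeric(hdr$Time) else NA_real_
    frames[[length(frames) + 1L]] <-
      simulation_frame(pos, types, cell = cell, pbc = pbc,
                       molecule_ids = mols, frame_index = fidx, time = time)
    fidx <- fidx + 1L
    i <- i + 2L + nat
  }
  frames
}

## --- LAMMPS text dump -----------------------------------------------------

read_lammps_lines <- function(lines) {
  frames <- list()
  i <- 1L
  fidx <- 0L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[[i]]))) { i <- i + 1L; next }
    if (!grepl("^ITEM: TIMESTEP", lines[[i]]))
      parse_error(i, "expected 'ITEM: TIMESTEP'")
    timestep <- as.numeric(trimws(lines[[i + 1L]]))
    if (!grepl("^ITEM: NUMBER OF ATOMS", lines[[i + 2L]]))
      parse_error(i + 2L, "expected 'ITEM: NUMBER OF ATOMS'")
    nat <- as.integer(trimws(lines[[i + 3L]]))
    if (is.na(nat) || nat < 1L) parse_error(i + 3L, "bad atom count")
    if (!grepl("^ITEM: BOX BOUNDS", lines[[i + 4L]]))
      parse_error(i + 4L, "expected 'ITEM: BOX BOUNDS'")
    triclinic <- grepl("xy xz yz", lines[[i + 4L]])
    bb <- lapply(lines[(i + 5L):(i + 7L)],
                 function(l) as.numeric(split_fields(l)))
    lo <- vapply(bb, `[`, 0, 1L); hi <- vapply(bb, `[`, 0, 2L)
    tilt <- if (triclinic) vapply(bb, `[`, 0, 3L) else c(0, 0, 0)
    xy <- tilt[1]; xz <- tilt[2]; yz <- tilt[3]
    if (triclinic) {
      ## LAMMPS stores bounding-box extents; recover cell edges
      lo[1] <- lo[1] - min(0, xy, xz, xy + xz)
      hi[1] <- hi[1] - max(0, xy, xz, xy + xz)
      lo[2] <- lo[2] - min(0, yz)
      hi[2] <- hi[2] - max(0, yz)
    }
    L <- hi - lo
    cell <- rbind(c(L[1], 0, 0), c(xy, L[2], 0), c(xz, yz, L[3]))
    if (!grepl("^ITEM: ATOMS", lines[[i + 8L]]))
      parse_error(i + 8L, "expected 'ITEM: ATOMS'")
    cols <- split_fields(sub("^ITEM: ATOMS", "", lines[[i + 8L]]))
    idx <- function(nm) match(nm, cols)
    c_id <- idx("id"); c_mol <- idx("mol")
    c_el <- if (!is.na(idx("element"))) idx("element") else idx("type")
    scaled <- !is.na(idx("xs"))
    cx <- if (scaled) idx("xs") else idx("x")
    cy <- if (scaled) idx("ys") else idx("y")
    cz <- if (scaled) idx("zs") else idx("z")
    if (is.na(c_el) || is.na(cx) || is.na(cy) || is.na(cz))
      parse_error(i + 8L, "ITEM: ATOMS must provide type/element and x y z (or xs ys zs)")
    body <- lines[(i + 9L):(i + 8L + nat)]
    toks <- strsplit(trimws(body), "[ \t]+")
    pos <- matrix(NA_real_, nat, 3L)
    types <- character(nat)
    mols <- if (!is.na(c_mol)) integer(nat) else NULL
    ids <- integer(nat)
    for (a in seq_len(nat)) {
      tk <- toks[[a]]
      ids[a] <- if (!is.na(c_id)) as.integer(tk[c_id]) else a
      types[a] <- tk[c_el]
      xyz <- as.numeric(c(tk[cx], tk[cy], tk[cz]))
      if (anyNA(xyz)) parse_error(i + 8L + a, "non-numeric coordinate")
      pos[a, ] <- xyz
      if (!is.null(mols)) mols[a] <- as.integer(tk[c_mol])
    }
    ord <- order(ids)
    pos <- pos[ord, , drop = FALSE]; types <- types[ord]
    if (!is.null(mols)) mols <- mols[ord]
    if (scaled) pos <- pos %*% cell
    else pos <- sweep(pos, 2L, lo)   # shift box origin to 0
    ## numeric LAMMPS types are kept as "T<k>" pseudo-elements unless they
    ## look like element symbols
    if (all(grepl("^[0-9]+$", types))) types <- paste0("T", types)
    else check_elements(types, paste0("frame ", fidx))
    frames[[length(frames) + 1L]] <-
      simulation_frame(pos, types, cell = cell, pbc = c(TRUE, TRUE, TRUE),
                       molecule_ids = mols, frame_index = fidx,
                       time = timestep)
    fidx <- fidx + 1L
    i <- i + 9L + nat
  }
  frames
}

#' Write trajectory frames to disk
#'
#' @param frames a single [simulation_frame()] or a list of them.
#' @param path output file path.
#' @param format `"extxyz"` or `"lammps_dump"`. LAMMPS output uses 1-based
#'   atom and molecule ids; extended XYZ carries molecule ids in a `mol`
#'   column when present.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, format = c("extxyz", "lammps_dump")) {
  format <- match.arg(format)
  if (inherits(frames, "simulation_frame")) frames <- list(frames)
  out <- character(0)
  for (fr in frames) {
    out <- c(out, switch(format,
                         extxyz = format_extxyz(fr),
                         lammps_dump = format_lammps(fr)))
  }
  writeLines(out, path)
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 12)

format_extxyz <- function(fr) {
  nat <- n_atoms(fr)
  hdr <- character(0)
  if (!is.null(fr$cell))
    hdr <- c(hdr, sprintf('Lattice="%s"',
                          paste(fmt_num(t(fr$cell)), collapse = " ")))
  props <- "species:S:1:pos:R:3"
  if (!is.null(fr$molecule_ids)) props <- paste0(props, ":mol:I:1")
  hdr <- c(hdr, paste0("Properties=", props),
           sprintf('pbc="%s"', paste(ifelse(fr$pbc, "T", "F"), collapse = " ")))
  if (!is.na(fr$time)) hdr <- c(hdr, sprintf("Time=%s", fmt_num(fr$time)))
  body <- vapply(seq_len(nat), function(a) {
    rec <- c(fr$atom_types[a], fmt_num(fr$positions[a, ]))
    if (!is.null(fr$molecule_ids)) rec <- c(rec, fr$molecule_ids[a])
    paste(rec, collapse = " ")
  }, character(1))
  c(as.character(nat), paste(hdr, collapse = " "), body)
}

format_lammps <- function(fr) {
  nat <- n_atoms(fr)
  cell <- fr$cell
  if (is.null(cell)) {
    ## non-periodic: bounding box with margin
    span <- apply(fr$positions, 2L, range)
    cell <- diag(span[2, ] - span[1, ] + 20)
  }
  tri <- any(abs(cell[upper.tri(cell)]) > 1e-12) ||
    any(abs(cell[lower.tri(cell)]) > 1e-12)
  xy <- cell[2, 1]; xz <- cell[3, 1]; yz <- cell[3, 2]
  lo <- c(0, 0, 0); hi <- c(cell[1, 1], cell[2, 2], cell[3, 3])
  mol <- fr$molecule_ids
  if (is.null(mol)) mol <- rep(1L, nat)
  mol1 <- mol - min(mol) + 1L         # 1-based on write
  bounds <- if (tri) {
    blo <- c(lo[1] + min(0, xy, xz, xy + xz), lo[2] + min(0, yz), lo[3])
    bhi <- c(hi[1] + max(0, xy, xz, xy + xz), hi[2] + max(0, yz), hi[3])
    c("ITEM: BOX BOUNDS xy xz yz pp pp pp",
      paste(fmt_num(c(blo[1], bhi[1], xy)), collapse = " "),
      paste(fmt_num(c(blo[2], bhi[2], xz)), collapse = " "),
      paste(fmt_num(c(blo[3], bhi[3], yz)), collapse = " "))
  } else {
    c("ITEM: BOX BOUNDS pp pp pp",
      paste(fmt_num(c(lo[1], hi[1])), collapse = " "),
      paste(fmt_num(c(lo[2], hi[2])), collapse = " "),
      paste(fmt_num(c(lo[3], hi[3])), collapse = " "))
  }
  body <- vapply(seq_len(nat), function(a) {
    paste(c(a, mol1[a], fr$atom_types[a], fmt_num(fr$positions[a, ])),
          collapse = " ")
  }, character(1))
  c("ITEM: TIMESTEP",
    as.character(if (is.na(fr$time)) fr$frame_index else fr$time),
    "ITEM: NUMBER OF ATOMS", as.character(nat),
    bounds,
    "ITEM: ATOMS id mol element x y z",
    body)
}
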