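#' C-alpha structure objects
#'
#' A `calpha_structure` represents a protein chain as one bead per residue:
#' residues are renumbered 1..N in chain order and each bead carries the 3-D
#' coordinates (in Angstrom) of its C-alpha atom.
#'
#' @param xyz numeric matrix, one row per residue, columns x/y/z in Angstrom.
#' @param chain_id chain label (single character string).
#' @param source free-text provenance, e.g. `"4AKE:A"` or `"synthetic"`.
#' @param linker_residues integer vector of residues that are engineered
#'   linkers (e.g. the glycine loop of a circular permutant) rather than part
#'   of the original chain; excluded from domain metrics.
#' @return an object of class `calpha_structure` with fields `xyz`,
#'   `residue_ids` (1..N), `chain_id`, `source`, `linker_residues`.
#' @export
calpha_structure <- function(xyz, chain_id = "A", source = "unknown",
                             linker_residues = integer(0)) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  if (nrow(xyz) < 4L) stop("structure must have at least 4 residues")
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  structure(list(xyz = xyz, residue_ids = seq_len(nrow(xyz)),
                 chain_id = chain_id, source = source,
                 linker_residues = as.integer(linker_residues)),
            class = "calpha_structure")
}

#' @export
print.calpha_structure <- function(x, ...) {
  cat(sprintf("calpha_structure: %d residues, chain %s, source %s\n",
              nrow(x$xyz), x$chain_id, x$source))
  invisible(x)
}

#' @export
length.calpha_structure <- function(x) nrow(x$xyz)

#' Read a C-alpha structure from PDB text
#'
#' Parses the ATOM records of a PDB file (via bio3d), keeps the CA atom of
#' every residue of the requested chain, resolves alternate locations to the
#' first occurrence, and renumbers residues sequentially 1..N (insertion
#' codes collapse onto the sequential numbering).
#'
#' @param pdb_text character: PDB-format text (single string or vector of
#'   lines), or a path to a PDB file.
#' @param chain chain identifier to extract.
#' @return a [calpha_structure].
#' @export
read_calpha_structure <- function(pdb_text, chain = "A") {
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) && file.exists(pdb_text)) {
    path <- pdb_text
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n")), path)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  chains <- unique(atoms$chain)
  if (!chain %in% chains) {
    stop(sprintf("chain '%s' not found; available chains: %s", chain,
                 paste(chains, collapse = ", ")))
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  # residue identity = resno + insertion code, in file order
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  resid <- paste0(atoms$resno, ins)
  resid_order <- unique(resid)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca_resid <- paste0(ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
  missing_ca <- setdiff(resid_order, ca_resid)
  if (length(missing_ca) > 0) {
    stop(sprintf("missing CA atom for residue(s): %s",
                 paste(missing_ca, collapse = ", ")))
  }
  # first occurrence per residue resolves alternate locations
  keep <- !duplicated(ca_resid)
  ca <- ca[keep, , drop = FALSE]
  ca <- ca[match(resid_order, ca_resid[keep]), , drop = FALSE]
  calpha_structure(cbind(ca$x, ca$y, ca$z), chain_id = chain,
                   source = paste0(basename(path), ":", chain))
}

#' Contact map constructor
#'
#' A `contact_map` holds the native contacts \{i, j, sigma, epsilon, label\}
#' of a chain of `n_residues` beads: `sigma` is the native C-alpha distance
#' in Angstrom, `epsilon` the contact strength in reduced energy units, and
#' `label` one of `intra:<domain>`, `interface:<domA>-<domB>`,
#' `closed-specific`, or `NA` when unclassified.
#'
#' @param contacts data.frame with columns `i`, `j`, `sigma` and optionally
#'   `epsilon` (default 1) and `label`.
#' @param n_residues chain length.
#' @return object of class `contact_map` (a data.frame with attribute
#'   `n_residues`).
#' @export
contact_map <- function(contacts, n_residues) {
  contacts <- as.data.frame(contacts)
  if (nrow(contacts) > 0) {
    if (any(contacts$i >= contacts$j)) stop("contacts must have i < j")
    if (any(contacts$i < 1 | contacts$j > n_residues))
      stop("contact residue index out of range [1, n_residues]")
    if (anyDuplicated(contacts[c("i", "j")]))
      stop("duplicate contact pairs")
    if (any(contacts$sigma <= 0)) stop("sigma must be positive")
  }
  if (is.null(contacts$epsilon)) contacts$epsilon <- rep(1, nrow(contacts))
  if (any(contacts$epsilon <= 0)) stop("epsilon must be positive")
  if (is.null(contacts$label)) contacts$label <- rep(NA_character_, nrow(contacts))
  contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
  rownames(contacts) <- NULL
  structure(contacts[c("i", "j", "sigma", "epsilon", "label")],
            n_residues = as.integer(n_residues),
            class = c("contact_map", "data.frame"))
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d contacts over %d residues\n",
              nrow(x), attr(x, "n_residues")))
  if (nrow(x) > 0) {
    lab <- table(ifelse(is.na(x$label), "(unlabelled)", x$label))
    for (nm in names(lab)) cat(sprintf("  %s: %d\n", nm, lab[[nm]]))
  }
  invisible(x)
}

#' Compute a native contact map from C-alpha geometry
#'
#' A residue pair (i, j) is a native contact when j - i >= `min_sep` and the
#' C-alpha distance is <= `cutoff`. `sigma` is set to the observed distance
#' and `epsilon` to 1. This is the package's reproducible stand-in for
#' atomistic contact determination; externally derived contact lists can be
#' ingested with [load_contact_list()] instead.
#'
#' @param structure a [calpha_structure].
#' @param cutoff distance cutoff in Angstrom (default 8.0).
#' @param min_sep minimum sequence separation (default 3).
#' @return a [contact_map].
#' @export
compute_contact_map <- function(structure, cutoff = 8.0, min_sep = 3L) {
  stopifnot(inherits(structure, "calpha_structure"), cutoff > 0, min_sep >= 1)
  n <- nrow(structure$xyz)
  d <- as.matrix(stats::dist(structure$xyz))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1] >= min_sep) & (d[idx] <= cutoff)
  contact_map(data.frame(i = idx[keep, 1], j = idx[keep, 2],
                         sigma = d[idx][keep]), n)
}

#' Load a native contact list from TSV text
#'
#' Expected dialect: comment/header lines start with `#`; data rows have
#' whitespace-separated columns `i j sigma [epsilon]` (epsilon defaults
#' to 1). Rows with i > j are an error (the canonical order is i < j).
#'
#' @param text TSV text (string, vector of lines, or file path).
#' @param n_residues chain length used for validation.
#' @return a [contact_map].
#' @export
load_contact_list <- function(text, n_residues) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  }
  lines <- trimws(lines)
  data_rows <- which(nzchar(lines) & !startsWith(lines, "#"))
  recs <- vector("list", length(data_rows))
  for (k in seq_along(data_rows)) {
    row <- data_rows[k]
    fields <- strsplit(lines[row], "[ \t]+")[[1]]
    if (length(fields) < 3)
      stop(sprintf("row %d: expected at least 3 columns (i j sigma)", row))
    vals <- suppressWarnings(as.numeric(fields[1:min(4, length(fields))]))
    if (any(is.na(vals)))
      stop(sprintf("row %d: non-numeric field", row))
    i <- vals[1]; j <- vals[2]; sigma <- vals[3]
    epsilon <- if (length(vals) >= 4) vals[4] else 1
    if (i >= j) stop(sprintf("row %d: requires i < j (got i=%g, j=%g)", row, i, j))
    if (i < 1 || j > n_residues)
      stop(sprintf("row %d: residue index out of range [1, %d]", row, n_residues))
    if (sigma <= 0) stop(sprintf("row %d: non-positive sigma", row))
    recs[[k]] <- c(i = i, j = j, sigma = sigma, epsilon = epsilon)
  }
  df <- as.data.frame(do.call(rbind, recs))
  if (is.null(df) || nrow(df) == 0)
    return(contact_map(data.frame(i = integer(0), j = integer(0),
                                  sigma = numeric(0)), n_residues))
  dup <- which(duplicated(df[c("i", "j")]))
  if (length(dup) > 0)
    stop(sprintf("row %d: duplicate contact pair (%d, %d)",
                 data_rows[dup[1]], df$i[dup[1]], df$j[dup[1]]))
  contact_map(df, n_residues)
}

#' Write a contact map as TSV
#'
#' Inverse of [load_contact_list()]: writes header `# i j sigma epsilon`
#' followed by one row per contact.
#'
#' @param cmap a [contact_map].
#' @param path output file path; when `NULL`, the text is returned invisibly
#'   as a character vector instead.
#' @export
write_contact_list <- function(cmap, path = NULL) {
  lines <- c("# i j sigma epsilon",
             sprintf("%d\t%d\t%.6f\t%.6f", cmap$i, cmap$j, cmap$sigma, cmap$epsilon))
  if (is.null(path)) return(invisible(lines))
  writeLines(lines, path)
  invisible(path)
}

#' Domain partition
#'
#' Maps domain names to ordered lists of closed residue intervals (1-based,
#' inclusive). A domain is *discontinuous* iff it has two or more intervals;
#' it is *inserted* iff its full span lies strictly inside the span of
#' another domain. Residues outside all domains (e.g. engineered linkers)
#' are unassigned and excluded from domain metrics.
#'
#' @param domains named list; each element a matrix/data.frame with two
#'   columns (start, end) or a vector `c(start, end)` for a single interval.
#' @return object of class `domain_partition`.
#' @export
domain_partition <- function(domains) {
  stopifnot(is.list(domains), !is.null(names(domains)), all(nzchar(names(domains))))
  doms <- lapply(domains, function(iv) {
    if (is.null(dim(iv))) iv <- matrix(iv, ncol = 2, byrow = TRUE)
    iv <- as.matrix(iv)
    storage.mode(iv) <- "integer"
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[, 2] < iv[, 1])) stop("interval end before start")
    if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop("overlapping intervals within a domain")
    colnames(iv) <- c("start", "end")
    iv
  })
  all_res <- unlist(lapply(doms, function(iv)
    unlist(apply(iv, 1, function(r) r[1]:r[2], simplify = FALSE))))
  if (anyDuplicated(all_res)) stop("intervals of different domains overlap")
  structure(doms, class = "domain_partition")
}

#' @export
print.domain_partition <- function(x, ...) {
  for (nm in names(x)) {
    iv <- x[[nm]]
    ivs <- paste(sprintf("%d-%d", iv[, 1], iv[, 2]), collapse = ", ")
    tags <- c(if (domain_is_discontinuous(x, nm)) "discontinuous",
              if (domain_is_inserted(x, nm)) "inserted")
    cat(sprintf("%s: %s%s\n", nm, ivs,
                if (length(tags)) paste0(" [", paste(tags, collapse = ", "), "]") else ""))
  }
  invisible(x)
}

#' @rdname domain_partition
#' @param partition a `domain_partition`.
#' @param name domain name.
#' @export
domain_is_discontinuous <- function(partition, name) {
  nrow(partition[[name]]) >= 2L
}

#' @rdname domain_partition
#' @export
domain_is_inserted <- function(partition, name) {
  span <- range(partition[[name]])
  for (other in setdiff(names(partition), name)) {
    o <- range(partition[[other]])
    if (o[1] < span[1] && span[2] < o[2]) return(TRUE)
  }
  FALSE
}

#' @rdname domain_partition
#' @param n_residues chain length for the lookup vector.
#' @return `residue_domains()`: character vector of length `n_residues` with
#'   the domain of each residue (`NA` when unassigned).
#' @export
residue_domains <- function(partition, n_residues) {
  out <- rep(NA_character_, n_residues)
  for (nm in names(partition)) {
    iv <- partition[[nm]]
    for (r in seq_len(nrow(iv))) out[iv[r, 1]:iv[r, 2]] <- nm
  }
  out
}

#' Read/write a domain partition as JSON
#'
#' The on-disk form is a JSON object mapping each domain name to a list of
#' `[start, end]` pairs.
#'
#' @param path file path.
#' @export
read_domain_partition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  domain_partition(lapply(obj, function(iv) matrix(unlist(iv), ncol = 2, byrow = !is.matrix(iv))))
}

#' @rdname read_domain_partition
#' @param partition a [domain_partition].
#' @export
write_domain_partition <- function(partition, path) {
  obj <- lapply(partition, function(iv)
    unname(apply(iv, 1, function(r) c(r[1], r[2]), simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' Label contacts by domain location
#'
#' Each contact becomes `intra:<dom>` when both residues are in one domain,
#' `interface:<domA>-<domB>` (names in canonical alphabetical order) when
#' they are in two different domains, and keeps an `NA` label when either
#' residue is outside all domains (linker residues). Contacts already
#' labelled `closed-specific` are left untouched.
#'
#' @param cmap a [contact_map].
#' @param partition a [domain_partition].
#' @return the contact map with labels filled in.
#' @export
classify_contacts <- function(cmap, partition) {
  n <- attr(cmap, "n_residues")
  dom <- residue_domains(partition, n)
  di <- dom[cmap$i]; dj <- dom[cmap$j]
  lab <- rep(NA_character_, nrow(cmap))
  both <- !is.na(di) & !is.na(dj)
  same <- both & di == dj
  lab[same] <- paste0("intra:", di[same])
  diff <- both & di != dj
  a <- pmin(di[diff], dj[diff]); b <- pmax(di[diff], dj[diff])
  lab[diff] <- paste0("interface:", a, "-", b)
  keep_closed <- !is.na(cmap$label) & cmap$label == "closed-specific"
  lab[keep_closed] <- "closed-specific"
  cmap$label <- lab
  cmap
}
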