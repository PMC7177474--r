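# Multi-model PDB reader/writer and TSV score tables.
#
# The reader is deliberately strict: ensembles must share one topology, so a
# malformed ATOM record or an atom-count/name mismatch between models is a
# hard error naming the offending line or atom, never a silent repair.

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "TIP", "TIP3", "SPC")

# Guess the element from the atom-name field when columns 77-78 are blank:
# strip leading digits, take the first character (standard PDB heuristic).
elementFromName <- function(name) {
  stripped <- sub("^[0-9']+", "", name)
  toupper(substr(stripped, 1L, 1L))
}

parseAtomLine <- function(line, lineno) {
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  line <- pad(line, 80)
  f <- function(a, b) substr(line, a, b)
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(trimws(f(a, b))))
    if (is.na(v))
      stop(sprintf("PDB format error at line %d: unparsable %s field '%s'",
                   lineno, what, trimws(f(a, b))), call. = FALSE)
    v
  }
  serial <- suppressWarnings(as.integer(trimws(f(7, 11))))
  if (is.na(serial)) serial <- NA_integer_
  name <- trimws(f(13, 16))
  if (!nzchar(name))
    stop(sprintf("PDB format error at line %d: empty atom name", lineno),
         call. = FALSE)
  resId <- suppressWarnings(as.integer(trimws(f(23, 26))))
  if (is.na(resId))
    stop(sprintf("PDB format error at line %d: unparsable residue number '%s'",
                 lineno, trimws(f(23, 26))), call. = FALSE)
  element <- trimws(f(77, 78))
  if (!nzchar(element)) element <- elementFromName(name)
  occ <- suppressWarnings(as.numeric(trimws(f(55, 60))))
  if (is.na(occ)) occ <- 1.0
  list(record = trimws(f(1, 6)), serial = serial, name = name,
       altLoc = trimws(f(17, 17)), resName = trimws(f(18, 20)),
       chain = trimws(f(22, 22)), resId = resId, iCode = trimws(f(27, 27)),
       x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
       occupancy = occ, element = toupper(element))
}

# Resolve alternate locations: keep the highest-occupancy altloc per atom,
# ties broken in favour of blank then "A" then alphabetical.
resolveAltlocs <- function(df) {
  if (all(df$altLoc == "")) return(df)
  key <- paste(df$chain, df$resId, df$name, sep = "\r")
  rank <- match(df$altLoc, c("", "A", sort(unique(df$altLoc))))
  ord <- order(key, -df$occupancy, rank)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df[order(df$row), , drop = FALSE]
}

parseModel <- function(lines, linenos, includeHet, keepHydrogens) {
  recs <- lapply(seq_along(lines),
                 function(i) parseAtomLine(lines[i], linenos[i]))
  df <- do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
  df$row <- seq_len(nrow(df))
  df <- df[!(df$resName %in% WATER_RESNAMES), , drop = FALSE]
  if (!includeHet) df <- df[df$record == "ATOM", , drop = FALSE]
  if (!keepHydrogens) df <- df[!(df$element %in% c("H", "D")), , drop = FALSE]
  if (any(nzchar(df$iCode)))
    stop(sprintf("insertion codes are not supported (first at residue %s%d%s)",
                 df$chain[nzchar(df$iCode)][1],
                 df$resId[nzchar(df$iCode)][1],
                 df$iCode[nzchar(df$iCode)][1]), call. = FALSE)
  df <- resolveAltlocs(df)
  df
}

#' Read a multi-model PDB file into a ConformerEnsemble
#'
#' Models delimited by `MODEL`/`ENDMDL` become conformers in file order; a
#' file with no `MODEL` records is read as a one-model ensemble. Waters are
#' always dropped; `HETATM` records and hydrogens are dropped by default.
#' All models must share an identical `(chain, resId, resName, name)`
#' topology.
#'
#' @param path path to a PDB file.
#' @param format only `"pdb"` is supported.
#' @param includeHet keep non-water `HETATM` records?
#' @param keepHydrogens keep hydrogen/deuterium atoms?
#' @returns a [ConformerEnsemble-class].
#' @export
#' @examples
#' gen <- generateLoopEnsemble(EnsembleSpec(nModels = 3, seed = 1))
#' f <- tempfile(fileext = ".pdb")
#' writeEnsemble(gen$ensemble, f)
#' readEnsemble(f)
readEnsemble <- function(path, format = c("pdb"), includeHet = FALSE,
                         keepHydrogens = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM") |
    trimws(rec) %in% c("ATOM", "HETATM")
  modelStart <- grep("^MODEL", lines)
  modelEnd <- grep("^ENDMDL", lines)
  if (length(modelStart) != length(modelEnd) ||
      (length(modelStart) && any(modelEnd < modelStart)))
    stop("malformed MODEL/ENDMDL records", call. = FALSE)

  if (length(modelStart) == 0L) {
    groups <- list(which(isAtom))
    ids <- "1"
  } else {
    groups <- mapply(function(s, e) intersect(which(isAtom), seq(s, e)),
                     modelStart, modelEnd, SIMPLIFY = FALSE)
    ids <- trimws(substr(lines[modelStart], 7, 80))
    ids[!nzchar(ids)] <- as.character(seq_along(ids))[!nzchar(ids)]
  }
  if (!length(groups[[1]])) stop("no ATOM records found", call. = FALSE)

  models <- lapply(groups, function(ix)
    parseModel(lines[ix], ix, includeHet, keepHydrogens))

  ref <- models[[1]]
  refKey <- paste(ref$chain, ref$resId, ref$resName, ref$name)
  nA <- nrow(ref)
  xyz <- array(NA_real_, c(nA, 3L, length(models)))
  for (m in seq_along(models)) {
    cur <- models[[m]]
    curKey <- paste(cur$chain, cur$resId, cur$resName, cur$name)
    if (nrow(cur) != nA || !identical(curKey, refKey)) {
      nshared <- min(nrow(cur), nA)
      diffAt <- which(curKey[seq_len(nshared)] != refKey[seq_len(nshared)])
      bad <- if (length(diffAt)) diffAt[1] else nshared + 1L
      badAtom <- if (bad <= nrow(cur)) curKey[bad] else refKey[bad]
      stop(sprintf(
        "topology error: model %s differs from model %s (first mismatch: atom '%s')",
        ids[m], ids[1], badAtom), call. = FALSE)
    }
    xyz[, , m] <- cbind(cur$x, cur$y, cur$z)
  }
  atoms <- data.frame(serial = ref$serial, name = ref$name,
                      resName = ref$resName, resId = ref$resId,
                      chain = ref$chain, element = ref$element,
                      stringsAsFactors = FALSE)
  ConformerEnsemble(atoms, xyz, modelIds = ids, source = path)
}

#' Write a ConformerEnsemble as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per conformer, coordinates in standard
#' `%8.3f` columns, terminated by `END`.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param path output file path.
#' @returns `path`, invisibly.
#' @export
writeEnsemble <- function(ensemble, path) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  if (nModels(ensemble) < 1L) stop("ensemble must be non-empty")
  xyz <- ensemble@coords
  if (any(xyz >= 10000 | xyz <= -1000))
    stop("coordinates do not fit PDB %8.3f columns (|x| too large)",
         call. = FALSE)
  at <- ensemble@atoms
  nm <- ifelse(nchar(at$name) >= 4L, at$name,
               paste0(" ", formatC(at$name, width = -3)))
  serial <- seq_len(nrow(at))
  out <- character(0)
  for (m in seq_len(nModels(ensemble))) {
    mid <- suppressWarnings(as.integer(ensemble@modelIds[m]))
    if (is.na(mid)) mid <- m
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, nm, at$resName, at$chain, at$resId,
      xyz[, 1, m], xyz[, 2, m], xyz[, 3, m], 1.0, 0.0, at$element)
    out <- c(out, sprintf("MODEL %8d", mid), lines, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a TSV table of model scores
#'
#' Expects a header with columns `model_id`, `dope` and `soap`
#' (case-insensitive); DOPE and SOAP are pseudo-energies produced by an
#' external modelling package, lower = better.
#'
#' @param path path to a tab-separated file.
#' @returns a data.frame with columns `model_id` (character), `dope`, `soap`
#'   (numeric), one row per model in file order.
#' @export
readScores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  nm <- tolower(names(raw))
  need <- c("model_id", "dope", "soap")
  missing <- setdiff(need, nm)
  if (length(missing))
    stop("score table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(model_id = trimws(raw[[which(nm == "model_id")[1]]]),
                    stringsAsFactors = FALSE)
  for (col in c("dope", "soap")) {
    txt <- trimws(raw[[which(nm == col)[1]]])
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val) & nzchar(txt) | !nzchar(txt))
    if (length(bad))
      stop(sprintf("score parse error at row %d: non-numeric %s value '%s'",
                   bad[1], col, txt[bad[1]]), call. = FALSE)
    out[[col]] <- val
  }
  out
}

#' Write a TSV table of model scores
#'
#' @param scores data.frame with columns model_id, dope, soap.
#' @param path output path.
#' @returns `path`, invisibly.
#' @export
writeScores <- function(scores, path) {
  stopifnot(all(c("model_id", "dope", "soap") %in% names(scores)))
  utils::write.table(scores[, c("model_id", "dope", "soap")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
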