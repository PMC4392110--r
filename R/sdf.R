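# SDF (MDL V2000) input and output, backed by ChemmineR.

# Split raw SDF lines into per-record chunks (each including its "$$$$"
# terminator).  A trailing chunk of only blank lines is dropped.
.split_sdf_records <- function(lines) {
  term <- grepl("^\\$\\$\\$\\$", lines)
  if (!length(lines)) return(list())
  rec_id <- cumsum(c(0L, utils::head(term, -1L))) + 1L
  chunks <- split(lines, rec_id)
  chunks <- unname(chunks)
  keep <- vapply(chunks, function(ch) any(nzchar(trimws(ch))) &&
                   !all(grepl("^\\$\\$\\$\\$", ch[nzchar(trimws(ch))])),
                 logical(1))
  chunks[keep]
}

.sdf_to_mol <- function(sdf, ordinal) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  sym <- sub("_[0-9]+$", "", rownames(ab))
  atoms <- data.frame(z = element_number(sym), aromatic = FALSE)
  bonds <- if (NROW(bb)) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               type = as.integer(bb[, 3]))
  } else {
    NULL
  }
  db <- ChemmineR::datablock(sdf)
  fields <- if (length(db)) {
    stats::setNames(as.character(db), names(db))
  } else {
    character()
  }
  name <- trimws(ChemmineR::header(sdf)[["Molecule_Name"]])
  id <- if (is.na(name) || !nzchar(name)) as.character(ordinal) else name
  molecule(id, atoms, bonds, fields)
}

#' Read molecule records from an SD file
#'
#' Records are returned in file order with every data field captured
#' verbatim as a string.  The molecule name line supplies the record id;
#' when it is empty, the 1-based record ordinal (as a string) is used so
#' that every record stays addressable in cluster output.  Hydrogens are
#' retained and aromaticity is not perceived at this stage; run
#' [prepare_molecule()] before computing similarities.
#'
#' @param file Path to an SD file, or a connection.
#' @param on_error `"abort"` stops at the first malformed record (the error
#'   names the record ordinal); `"skip"` drops malformed records with a
#'   warning and keeps going.
#' @return A list of `aap_mol` records (empty list for an empty stream).
#' @seealso [write_sdf()]
#' @export
read_sdf <- function(file, on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  lines <- readLines(file, warn = FALSE)
  chunks <- .split_sdf_records(lines)
  out <- vector("list", length(chunks))
  ok <- logical(length(chunks))
  for (i in seq_along(chunks)) {
    mol <- tryCatch({
      ss <- methods::as(methods::new("SDFstr", a = chunks[i]), "SDFset")
      .sdf_to_mol(ss[[1L]], i)
    }, error = function(e) e, warning = function(w) w)
    if (inherits(mol, "condition")) {
      msg <- sprintf("SDF record %d: malformed connection table (%s)", i,
                     conditionMessage(mol))
      if (on_error == "abort") stop(msg) else warning(msg, call. = FALSE)
    } else {
      out[[i]] <- mol
      ok[i] <- TRUE
    }
  }
  out[ok]
}

#' Write molecule records to an SD file
#'
#' The output round-trips: re-reading reproduces atom counts, the bond
#' list, and all data fields.  Each record is terminated with `$$$$`.
#'
#' @param mols An `aap_mol` or list of them.
#' @param file Output path or connection.
#' @return Invisibly, the input `mols`.
#' @seealso [read_sdf()]
#' @export
write_sdf <- function(mols, file) {
  if (inherits(mols, "aap_mol")) mols <- list(mols)
  for (m in mols) {
    if (length(m$fields) &&
        any(grepl("$$$$", m$fields, fixed = TRUE) |
              grepl("$$$$", names(m$fields), fixed = TRUE))) {
      stop(sprintf(
        "record '%s': data field contains the record terminator '$$$$'",
        m$id))
    }
  }
  if (!length(mols)) {
    writeLines(character(), file)
    return(invisible(mols))
  }
  sdfs <- lapply(mols, .as_chemmine_sdf)
  ss <- methods::new("SDFset", SDF = sdfs,
                     ID = vapply(mols, function(m) m$id, character(1)))
  ChemmineR::write.SDF(ss, file, cid = FALSE)
  invisible(mols)
}
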