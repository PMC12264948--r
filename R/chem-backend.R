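#' RDKit chemistry back end
#'
#' All chemistry I/O (SMILES parsing, standardization, InChI keys, SDF
#' writing) is delegated to RDKit through the bundled helper script
#' `inst/python/somhelper.py`, invoked batch-wise so a whole input table
#' costs a single interpreter start. The interpreter is resolved from the
#' `somannot.python` option, then `python`, then `python3` on the PATH.
#'
#' @name chem-backend
#' @keywords internal
NULL

the_cache <- new.env(parent = emptyenv())

som_python <- function() {
  opt <- getOption("somannot.python")
  if (!is.null(opt)) return(opt)
  for (cand in c("python", "python3")) {
    path <- Sys.which(cand)
    if (nzchar(path)) return(unname(path))
  }
  rlang::abort("No python interpreter found on PATH; install RDKit-enabled Python.")
}

som_helper <- function() {
  path <- system.file("python", "somhelper.py", package = "somannot")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is mapped directly
    path <- system.file("inst", "python", "somhelper.py", package = "somannot")
  }
  if (!nzchar(path)) rlang::abort("somhelper.py not found in the installed package.")
  path
}

run_helper <- function(args) {
  status <- system2(som_python(), c(shQuote(som_helper()), args),
    stdout = TRUE, stderr = TRUE
  )
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    rlang::abort(c("Chemistry helper failed.", paste(status, collapse = "\n")))
  }
  invisible(NULL)
}

molgraph_from_record <- function(rec) {
  atoms <- tibble::tibble(
    element = vapply(rec$atoms, `[[`, character(1), "el"),
    charge = vapply(rec$atoms, `[[`, integer(1), "chg"),
    n_h = vapply(rec$atoms, `[[`, integer(1), "nh"),
    aromatic = vapply(rec$atoms, `[[`, logical(1), "arom"),
    in_ring = vapply(rec$atoms, `[[`, logical(1), "ring"),
    map = vapply(rec$atoms, `[[`, integer(1), "map")
  )
  if (length(rec$bonds) > 0) {
    bonds <- tibble::tibble(
      i = vapply(rec$bonds, `[[`, integer(1), "i") + 1L,
      j = vapply(rec$bonds, `[[`, integer(1), "j") + 1L,
      order = vapply(rec$bonds, `[[`, integer(1), "order"),
      aromatic = vapply(rec$bonds, `[[`, logical(1), "arom"),
      in_ring = vapply(rec$bonds, `[[`, logical(1), "ring")
    )
  } else {
    bonds <- tibble::tibble(
      i = integer(), j = integer(), order = integer(),
      aromatic = logical(), in_ring = logical()
    )
  }
  new_molgraph(atoms, bonds, inchikey = rec$inchikey, smiles = rec$smiles)
}

#' Parse and standardize a batch of SMILES strings
#'
#' Runs the full standardization cascade (parent-fragment extraction,
#' normalization, neutralization, canonical tautomer) on each input and
#' returns one element per SMILES: a [new_molgraph()] on success or a
#' character rejection reason (`"unparseable"` or `"key_failure"`).
#'
#' @param smiles Character vector of SMILES strings (atom maps allowed and
#'   preserved into the `map` atom column).
#' @return A list parallel to `smiles`.
#' @keywords internal
chem_standardize <- function(smiles) {
  if (length(smiles) == 0) return(list())
  tsv <- tempfile(fileext = ".tsv")
  out <- tempfile(fileext = ".json")
  on.exit(unlink(c(tsv, out)), add = TRUE)
  writeLines(paste(seq_along(smiles), smiles, sep = "\t"), tsv, useBytes = TRUE)
  run_helper(c("standardize", shQuote(tsv), shQuote(out)))
  recs <- jsonlite::fromJSON(out, simplifyVector = FALSE)
  res <- vector("list", length(smiles))
  for (rec in recs) {
    k <- as.integer(rec$id)
    res[[k]] <- if (isTRUE(rec$ok)) molgraph_from_record(rec) else rec$error
  }
  # blank/missing rows never reach the helper
  for (k in which(vapply(res, is.null, logical(1)))) res[[k]] <- "unparseable"
  res
}

#' Standardize with memoization on the SMILES string
#' @noRd
chem_standardize_cached <- function(smiles) {
  key <- paste0("mol:", smiles)
  hit <- vapply(key, function(k) !is.null(the_cache[[k]]), logical(1))
  if (any(!hit)) {
    fresh <- chem_standardize(smiles[!hit])
    for (k in seq_along(fresh)) assign(key[!hit][k], fresh[[k]], envir = the_cache)
  }
  lapply(key, function(k) the_cache[[k]])
}

#' Write molecules to an SD file (V2000) with properties
#'
#' @param records List of lists with elements `smiles`, `name`, `props`
#'   (named list of property fields, e.g. `SOMS`, `RULE`).
#' @param path Output file path.
#' @keywords internal
chem_write_sdf <- function(records, path) {
  spec <- tempfile(fileext = ".json")
  on.exit(unlink(spec), add = TRUE)
  jsonlite::write_json(
    list(path = path, records = records),
    spec,
    auto_unbox = TRUE, null = "null"
  )
  run_helper(c("write_sdf", shQuote(spec)))
  invisible(path)
}
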