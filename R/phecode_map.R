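#' Load a phecode map table
#'
#' Reads one or more delimited map files relating ICD-9-CM/ICD-10-CM codes to
#' phecodes, phenotype names, and phecode categories, and normalizes them to
#' a single table. Column names are configurable so the two published map
#' layouts (which differ in header dialect) can be loaded without editing the
#' files; the bundled ~60-row synthetic map uses the canonical names.
#'
#' @param paths one or more CSV file paths.
#' @param columns named character vector mapping the canonical names
#'   (code_system, icd_code, phecode, phenotype, category) to the column
#'   names found in the files.
#' @return data.frame with columns code_system, icd_code, phecode, phenotype,
#'   category. Exact duplicate rows are dropped; the number dropped is stored
#'   in attribute `n_deduplicated`. ICD codes are stripped of surrounding
#'   whitespace; decimal points are preserved.
#' @export
load_phecode_map <- function(paths,
                             columns = c(code_system = "code_system",
                                         icd_code = "icd_code",
                                         phecode = "phecode",
                                         phenotype = "phenotype",
                                         category = "category")) {
  canonical <- c("code_system", "icd_code", "phecode", "phenotype", "category")
  stopifnot(all(canonical %in% names(columns)))
  tabs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("phecode map file not found: ", p, call. = FALSE)
    tab <- utils::read.csv(p, stringsAsFactors = FALSE, colClasses = "character")
    missing <- setdiff(unname(columns[canonical]), names(tab))
    if (length(missing) > 0)
      stop(sprintf("phecode map file '%s' lacks required column(s): %s",
                   p, paste(missing, collapse = ", ")), call. = FALSE)
    out <- tab[, unname(columns[canonical])]
    names(out) <- canonical
    out
  })
  map <- do.call(rbind, tabs)
  map$icd_code <- trimws(map$icd_code)
  map$code_system <- trimws(map$code_system)
  bad <- !map$code_system %in% c("ICD9CM", "ICD10CM")
  if (any(bad))
    stop("unknown code_system value(s): ",
         paste(unique(map$code_system[bad]), collapse = ", "), call. = FALSE)
  map[is.na(map$category), "category"] <- ""
  n0 <- nrow(map)
  map <- unique(map)
  rownames(map) <- NULL
  attr(map, "n_deduplicated") <- n0 - nrow(map)
  map
}

#' Map diagnosis events to phecode phenotypes
#'
#' Joins ICD events to the map by exact (code_system, code) equality and
#' collapses to one row per (person, phenotype), however many ICD events
#' support it. Phecodes without a category are excluded from analyses; codes
#' absent from the map are counted, never fatal.
#'
#' @param diagnoses data.frame with person_id, code_system, code.
#' @param map a table from [load_phecode_map()].
#' @return list with `assignments` (data.frame person_id, phenotype, sorted)
#'   and `unmapped` (data.frame code_system, code, n, reason in
#'   {not_in_map, excluded_no_category}).
#' @export
map_diagnoses <- function(diagnoses, map) {
  if (nrow(diagnoses) == 0) {
    return(list(assignments = data.frame(person_id = character(),
                                         phenotype = character(),
                                         stringsAsFactors = FALSE),
                unmapped = data.frame(code_system = character(),
                                      code = character(), n = integer(),
                                      reason = character(),
                                      stringsAsFactors = FALSE)))
  }
  key_dx <- paste(diagnoses$code_system, diagnoses$code, sep = "\r")
  key_map <- paste(map$code_system, map$icd_code, sep = "\r")
  usable <- map$category != ""
  # multi-match join: an ICD code may map to several phecodes, all retained
  hit_rows <- split(which(usable), key_map[usable])
  excluded_keys <- unique(key_map[!usable])
  matched <- key_dx %in% names(hit_rows)
  excluded <- !matched & key_dx %in% excluded_keys
  unmatched <- !matched & !excluded
  unmapped <- rbind(
    count_codes(diagnoses[excluded, , drop = FALSE], "excluded_no_category"),
    count_codes(diagnoses[unmatched, , drop = FALSE], "not_in_map"))
  if (!any(matched)) {
    return(list(assignments = data.frame(person_id = character(),
                                         phenotype = character(),
                                         stringsAsFactors = FALSE),
                unmapped = unmapped))
  }
  dxm <- diagnoses[matched, , drop = FALSE]
  idx <- hit_rows[key_dx[matched]]
  assignments <- data.frame(
    person_id = rep(dxm$person_id, lengths(idx)),
    phenotype = map$phenotype[unlist(idx, use.names = FALSE)],
    stringsAsFactors = FALSE)
  assignments <- unique(assignments)
  assignments <- assignments[order(assignments$person_id, assignments$phenotype), ]
  rownames(assignments) <- NULL
  list(assignments = assignments, unmapped = unmapped)
}

#' @keywords internal
count_codes <- function(dx, reason) {
  if (nrow(dx) == 0) {
    return(data.frame(code_system = character(), code = character(),
                      n = integer(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(n = dx$person_id),
                          by = list(code_system = dx$code_system, code = dx$code),
                          FUN = length)
  agg$reason <- reason
  agg[order(agg$code_system, agg$code), ]
}

#' Build the binary patient-by-phenotype matrix
#'
#' One-hot encodes phenotype assignments over a fixed patient list. Patients
#' with no phenotype get all-zero rows. Phenotypes in `exclude_phenotypes`
#' (by default the AD-defining phenotype, to avoid tautological case/control
#' signal) are dropped from the column axis. Rows and columns are sorted
#' lexicographically for deterministic serialization.
#'
#' @param assignments data.frame person_id, phenotype (from [map_diagnoses()]).
#' @param person_ids character vector of all patients the matrix must cover.
#' @param exclude_phenotypes phenotype names removed from the column axis.
#' @return integer 0/1 matrix with person_ids as rownames and phenotype names
#'   as colnames.
#' @export
build_phenotype_matrix <- function(assignments, person_ids,
                                   exclude_phenotypes = "Alzheimer's disease") {
  person_ids <- sort(unique(as.character(person_ids)))
  unknown <- setdiff(assignments$person_id, person_ids)
  if (length(unknown) > 0)
    stop("assignment(s) reference unknown person_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  keep <- !assignments$phenotype %in% exclude_phenotypes
  assignments <- assignments[keep, , drop = FALSE]
  phenos <- sort(unique(assignments$phenotype))
  m <- matrix(0L, nrow = length(person_ids), ncol = length(phenos),
              dimnames = list(person_ids, phenos))
  if (nrow(assignments) > 0) {
    m[cbind(match(assignments$person_id, person_ids),
            match(assignments$phenotype, phenos))] <- 1L
  }
  m
}
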