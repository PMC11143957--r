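#' Validate a table of twin-family records
#'
#' Checks that a data frame carries the canonical family-wide columns
#' (`family_id`, `zygosity`, `pgs_mother`, `pgs_father`, `pgs_twin1`,
#' `pgs_twin2`, `pheno_twin1`, `pheno_twin2`), normalizes zygosity codes to
#' `"MZ"`/`"DZ"`, coerces measurement columns to numeric, and errors on
#' duplicated family ids. Families with all six measurement slots missing
#' are unusable for the likelihood; they are dropped with a message.
#'
#' @param records A data frame, one row per family.
#' @param drop_unusable Drop rows with all six measurement slots missing
#'   (default `TRUE`).
#' @return The validated (possibly row-reduced) data frame.
#' @export
validate_family_records <- function(records, drop_unusable = TRUE) {
  stopifnot(is.data.frame(records))
  need <- c("family_id", "zygosity", .obs_vars)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[need]
  if (anyDuplicated(records$family_id))
    stop("duplicated family_id: ",
         paste(unique(records$family_id[duplicated(records$family_id)]),
               collapse = ", "))
  records$zygosity <- .normalize_zygosity(records$zygosity)
  for (v in .obs_vars) {
    x <- records[[v]]
    if (!is.numeric(x)) {
      xn <- suppressWarnings(as.numeric(as.character(x)))
      bad <- !is.na(x) & x != "" & is.na(xn)
      if (any(bad))
        stop("non-numeric value(s) in column ", v, ", e.g. row ",
             which(bad)[1])
      x <- xn
    }
    records[[v]] <- as.numeric(x)
  }
  usable <- rowSums(!is.na(as.matrix(records[.obs_vars]))) > 0
  if (drop_unusable && any(!usable)) {
    message(sum(!usable), " unusable famil",
            if (sum(!usable) == 1) "y" else "ies",
            " with no observed data dropped")
    records <- records[usable, , drop = FALSE]
  }
  rownames(records) <- NULL
  records
}

#' Read a family-wide CSV of twin-family records
#'
#' Reads one row per family. Column names in the file can be mapped to the
#' canonical names through `schema`, a named character vector or list of
#' the form `c(canonical = "file_column")`; canonical names are
#' `family_id`, `zygosity`, `pgs_mother`, `pgs_father`, `pgs_twin1`,
#' `pgs_twin2`, `pheno_twin1`, `pheno_twin2`. Missing entries may be coded
#' as empty fields or any of the `na_strings` sentinels.
#'
#' @param path Path to a CSV file.
#' @param schema Optional column-name map; `NULL` means the file already
#'   uses the canonical names.
#' @param na_strings Sentinels to treat as missing (default `""` and
#'   `"NA"`).
#' @param quiet Suppress the missingness-pattern message.
#' @return A validated data frame of family records. The table of
#'   missingness patterns is attached as attribute `"patterns"`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("family_id,zygosity,pgs_mother,pgs_father,pgs_twin1,pgs_twin2,pheno_twin1,pheno_twin2",
#'              "F1,MZ,0.1,,0.3,0.3,1.2,0.9"), f)
#' read_family_table(f, quiet = TRUE)
#' @export
read_family_table <- function(path, schema = NULL,
                              na_strings = c("", "NA"), quiet = FALSE) {
  raw <- read.csv(path, na.strings = na_strings,
                  stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty family table: ", path)
    out <- data.frame(family_id = character(), zygosity = character(),
                      pgs_mother = numeric(), pgs_father = numeric(),
                      pgs_twin1 = numeric(), pgs_twin2 = numeric(),
                      pheno_twin1 = numeric(), pheno_twin2 = numeric())
    return(out)
  }
  if (!is.null(schema)) {
    schema <- unlist(schema)
    missing_cols <- setdiff(schema, names(raw))
    if (length(missing_cols))
      stop("column(s) named in schema not found in file: ",
           paste(missing_cols, collapse = ", "))
    for (canon in names(schema)) names(raw)[names(raw) == schema[[canon]]] <- canon
  }
  out <- validate_family_records(raw)
  pat <- missingness_patterns(out)
  if (!quiet)
    message("read ", nrow(out), " families; ", nrow(pat),
            " missingness pattern(s)")
  attr(out, "patterns") <- pat
  out
}

#' Tabulate missingness patterns
#'
#' @param records Validated family records.
#' @return A data frame with one row per observed-variable pattern and
#'   zygosity group, with the count of families.
#' @export
missingness_patterns <- function(records) {
  M <- as.matrix(records[.obs_vars])
  obs <- !is.na(M)
  key <- apply(obs, 1, function(r)
    paste(ifelse(r, substr(.obs_vars, 1, 1), "."), collapse = ""))
  tab <- as.data.frame(table(zygosity = records$zygosity, pattern = key),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[3] <- "n_families"
  rownames(tab) <- NULL
  tab
}

#' Propagate MZ twin genotypes to the ungenotyped co-twin
#'
#' MZ twins carry identical genomes, so a polygenic score observed for one
#' MZ twin is also the co-twin's score. For MZ families with exactly one
#' observed twin PGS the value is copied to the co-twin; DZ families are
#' never touched. MZ families where both twin PGS are observed but differ
#' by more than `tol` draw a warning (the values are left as-is).
#'
#' Idempotent: applying it twice changes nothing.
#'
#' @param records Validated family records.
#' @param tol Tolerance for the equal-MZ-PGS check (default `1e-6`).
#' @param quiet Suppress the propagation-count message.
#' @return The records with MZ co-twin PGS filled in; the number of
#'   propagated values is attached as attribute `"n_propagated"`.
#' @export
propagate_mz_genotypes <- function(records, tol = 1e-6, quiet = FALSE) {
  records <- validate_family_records(records, drop_unusable = FALSE)
  mz <- records$zygosity == "MZ"
  t1 <- records$pgs_twin1; t2 <- records$pgs_twin2
  both <- mz & !is.na(t1) & !is.na(t2)
  if (any(both & abs(t1 - t2) > tol))
    warning(sum(both & abs(t1 - t2) > tol, na.rm = TRUE),
            " MZ famil(ies) with unequal observed twin PGS left unchanged")
  fill1 <- mz & is.na(t1) & !is.na(t2)
  fill2 <- mz & !is.na(t1) & is.na(t2)
  records$pgs_twin1[fill1] <- t2[fill1]
  records$pgs_twin2[fill2] <- t1[fill2]
  n_prop <- sum(fill1) + sum(fill2)
  if (!quiet) message("propagated ", n_prop, " MZ co-twin PGS value(s)")
  attr(records, "n_propagated") <- n_prop
  records
}
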