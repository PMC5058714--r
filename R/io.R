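# Readers/writers for the on-disk formats: expression TSV (genes x samples),
# MAF-lite mutation TSV, GMT gene sets, driver registry TSV.  No statistics
# here; loaders validate and never silently drop rows.

#' Read a normalized expression matrix
#'
#' Expects a TSV with a header row of sample identifiers and gene identifiers
#' in the first column.  Values must be numeric and complete; missing values
#' are rejected (the expected inputs are normalized, median-centered matrices
#' with no gaps).
#'
#' @param path TSV file path.
#' @return A numeric matrix, genes as rows, with unique row and column names.
#' @export
read_expression <- function(path) {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path)
  stop_if(length(lines) < 2,
          sprintf("expression file %s is empty or has no data rows", path))
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  stop_if(ncol(df) < 2, "expression file needs a gene column plus >=1 sample")
  genes <- df[[1]]
  samples <- colnames(df)[-1]
  dup <- unique(genes[duplicated(genes)])
  stop_if(length(dup) > 0,
          sprintf("duplicated gene ids: %s", paste(dup, collapse = ", ")))
  dup <- unique(samples[duplicated(samples)])
  stop_if(length(dup) > 0,
          sprintf("duplicated sample ids: %s", paste(dup, collapse = ", ")))
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1L]]) & df[[j + 1L]] != "NA")
    stop_if(length(bad) > 0,
            sprintf("non-numeric value at gene %s, sample %s",
                    genes[bad[1]], samples[j]))
    vals[, j] <- v
  }
  stop_if(anyNA(vals), "expression matrix contains missing values")
  message(sprintf("read_expression: %d genes x %d samples from %s",
                  nrow(vals), ncol(vals), path))
  vals
}

#' Write an expression matrix (or any matrix) as TSV
#'
#' Inverse of [read_expression()]; numbers are written with 12 significant
#' digits so a read/write cycle round-trips.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param rowname_header Header of the first (row-name) column.
#' @export
write_expression <- function(mat, path, rowname_header = "gene") {
  df <- data.frame(format(rownames(mat), trim = TRUE),
                   apply(mat, 2, format_num), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(rowname_header, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_num <- function(x) formatC(x, digits = 12, format = "g")

# default mapping from MAF-style consequence tokens to the closed
# {PAM, other} vocabulary; "protein-affecting mutation" covers missense,
# nonsense, frameshift and splice-site changes
default_effect_dialect <- function() {
  c(missense = "PAM", nonsense = "PAM", frameshift = "PAM", splice = "PAM",
    silent = "other", PAM = "PAM", other = "other")
}

#' Read a somatic mutation catalog (MAF-lite)
#'
#' Expects a TSV with columns `sample`, `gene`, `effect`.  Effect tokens are
#' mapped onto the closed vocabulary `{PAM, other}` via a dialect table
#' (default: missense/nonsense/frameshift/splice are protein-affecting,
#' silent is not).  Duplicate records collapse to one.
#'
#' @param path TSV file path.
#' @param dialect Named character vector mapping effect tokens to
#'   `"PAM"`/`"other"`.
#' @param strict If `TRUE` (default) an unmapped token is an error; otherwise
#'   it maps to `"other"` with a warning.
#' @return A `mutation_catalog`: data frame with columns
#'   `sample`, `gene`, `effect`.
#' @export
read_mutations <- function(path, dialect = default_effect_dialect(),
                           strict = TRUE) {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("sample", "gene", "effect")
  miss <- setdiff(need, colnames(df))
  stop_if(length(miss) > 0,
          sprintf("mutation file missing columns: %s",
                  paste(miss, collapse = ", ")))
  n_in <- nrow(df)
  cat_ <- mutation_catalog(df$sample, df$gene, df$effect,
                           dialect = dialect, strict = strict)
  message(sprintf(
    "read_mutations: %d records parsed from %s (%d after collapsing duplicates)",
    n_in, path, nrow(cat_)))
  cat_
}

#' Construct a mutation catalog from vectors
#'
#' @param sample,gene,effect Character vectors of equal length.
#' @inheritParams read_mutations
#' @return A `mutation_catalog` data frame.
#' @export
mutation_catalog <- function(sample, gene, effect,
                             dialect = default_effect_dialect(),
                             strict = TRUE) {
  stopifnot(length(sample) == length(gene), length(gene) == length(effect))
  mapped <- unname(dialect[effect])
  if (anyNA(mapped)) {
    bad <- sort(unique(effect[is.na(mapped)]))
    if (strict) {
      stop(sprintf("unmapped mutation effect token(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("unmapped effect token(s) mapped to 'other': %s",
                    paste(bad, collapse = ", ")))
    mapped[is.na(mapped)] <- "other"
  }
  df <- data.frame(sample = as.character(sample), gene = as.character(gene),
                   effect = mapped, stringsAsFactors = FALSE)
  df <- unique(df)
  df <- df[order(df$sample, df$gene, df$effect), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mutation_catalog", "data.frame")
  df
}

#' Per-sample sets of PAM-mutated genes
#'
#' @param catalog A `mutation_catalog`.
#' @param samples Optional sample ids to include (absent samples get empty
#'   sets).
#' @return Named list, sample id -> character vector of genes with at least
#'   one protein-affecting mutation.
#' @export
pam_sets <- function(catalog, samples = NULL) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  pam <- catalog[catalog$effect == "PAM", , drop = FALSE]
  sets <- split(pam$gene, factor(pam$sample, levels = unique(pam$sample)))
  sets <- lapply(sets, unique)
  if (!is.null(samples)) {
    out <- stats::setNames(vector("list", length(samples)), samples)
    for (s in samples) out[[s]] <- if (s %in% names(sets)) sets[[s]] else character()
    return(out)
  }
  sets
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Repeated members within a set are deduplicated; duplicate set names are an
#' error.
#'
#' @param path GMT file path.
#' @param collection_name Name of the collection (default: file base name).
#' @param category One of `"tf_targets"`, `"pathway"`,
#'   `"oncogenic_signature"`.
#' @param controllers Optional named character vector, set name -> controller
#'   gene.  For `tf_targets` collections the controller defaults to the set
#'   name (the TF itself).
#' @return A `gene_set_collection`.
#' @export
read_gene_sets <- function(path,
                           collection_name = sub("\\.gmt$", "", basename(path)),
                           category = c("tf_targets", "pathway",
                                        "oncogenic_signature"),
                           controllers = NULL) {
  category <- match.arg(category)
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  stop_if(length(lines) == 0, sprintf("GMT file %s is empty", path))
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    stop_if(length(fields) < 3,
            sprintf("GMT line %d has %d field(s); need name, description, members",
                    i, length(fields)))
    nm <- fields[1]
    stop_if(nm %in% names(sets), sprintf("duplicate set name '%s' (line %d)", nm, i))
    sets[[nm]] <- unique(fields[-(1:2)])
    descs[nm] <- fields[2]
  }
  message(sprintf("read_gene_sets: %d sets from %s", length(sets), path))
  gene_set_collection(collection_name, category, sets,
                      controllers = controllers, descriptions = descs)
}

#' Construct a gene-set collection
#'
#' @param collection_name Collection identifier.
#' @param category Set category (`tf_targets`, `pathway`,
#'   `oncogenic_signature`).
#' @param sets Named list of character vectors (members).
#' @param controllers Optional named character vector, set -> controller gene.
#' @param descriptions Optional named character vector of set descriptions.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(collection_name, category, sets,
                                controllers = NULL, descriptions = NULL) {
  category <- match.arg(category,
                        c("tf_targets", "pathway", "oncogenic_signature"))
  stop_if(is.null(names(sets)) || any(!nzchar(names(sets))),
          "every gene set needs a name")
  stop_if(anyDuplicated(names(sets)) > 0, "duplicate set names")
  stop_if(any(lengths(sets) == 0), "empty gene sets are not allowed")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(controllers) && category == "tf_targets") {
    controllers <- stats::setNames(names(sets), names(sets))
  }
  structure(list(name = collection_name, category = category, sets = sets,
                 controllers = controllers, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s' (%s): %d sets, sizes %d-%d\n",
              x$name, x$category, length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Write gene sets as GMT
#'
#' @param collection A `gene_set_collection`, or a named list of character
#'   vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(collection, path) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  descs <- if (inherits(collection, "gene_set_collection") &&
               !is.null(collection$descriptions)) collection$descriptions
           else stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, if (nm %in% names(descs)) descs[[nm]] else "na", sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a driver/CRF gene registry
#'
#' TSV with header columns `gene`, `is_driver`, `is_crf`, `mode`
#' (`LoF`/`Act`/`unknown`).  Duplicate gene rows with conflicting flags are
#' an error.
#'
#' @param path TSV file path.
#' @return A `driver_registry` data frame.
#' @export
read_registry <- function(path) {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("gene", "is_driver", "is_crf", "mode")
  miss <- setdiff(need, colnames(df))
  stop_if(length(miss) > 0,
          sprintf("registry missing columns: %s", paste(miss, collapse = ", ")))
  reg <- driver_registry(df$gene, as.logical(df$is_driver),
                         as.logical(df$is_crf), df$mode)
  message(sprintf("read_registry: %d genes from %s", nrow(reg), path))
  reg
}

#' Construct a driver registry
#'
#' @param gene Gene identifiers.
#' @param is_driver,is_crf Logical flags.
#' @param mode Driver mode: `"LoF"`, `"Act"` or `"unknown"`.
#' @return A `driver_registry` data frame.
#' @export
driver_registry <- function(gene, is_driver, is_crf, mode = "unknown") {
  df <- data.frame(gene = as.character(gene),
                   is_driver = as.logical(is_driver),
                   is_crf = as.logical(is_crf),
                   mode = as.character(mode), stringsAsFactors = FALSE)
  stop_if(anyNA(df$is_driver) || anyNA(df$is_crf),
          "is_driver/is_crf must be TRUE/FALSE")
  stop_if(!all(df$mode %in% c("LoF", "Act", "unknown")),
          "mode must be one of LoF, Act, unknown")
  df <- unique(df)
  dup <- unique(df$gene[duplicated(df$gene)])
  stop_if(length(dup) > 0,
          sprintf("conflicting duplicate registry rows for: %s",
                  paste(dup, collapse = ", ")))
  df <- df[order(df$gene), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("driver_registry", "data.frame")
  df
}

#' Driver-CRF and non-CRF-driver gene sets of a registry
#'
#' @param registry A `driver_registry`.
#' @return List with `driver_crfs` and `noncrf_drivers` character vectors.
#' @export
registry_sets <- function(registry) {
  stopifnot(inherits(registry, "driver_registry"))
  list(driver_crfs = registry$gene[registry$is_driver & registry$is_crf],
       noncrf_drivers = registry$gene[registry$is_driver & !registry$is_crf])
}

#' Write a result table as TSV
#'
#' Stable column order, deterministic row order (rows sorted by the first
#' column unless `sort_rows = FALSE`), numbers at 12 significant digits.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param sort_rows Sort rows by the first column (default `TRUE`).
#' @export
write_table <- function(df, path, sort_rows = TRUE) {
  out <- as.data.frame(df, stringsAsFactors = FALSE)
  if (sort_rows && nrow(out) > 1) out <- out[order(out[[1]]), , drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV result table
#'
#' @param path File path.
#' @return Data frame with columns type-converted.
#' @export
read_table <- function(path) {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  utils::read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
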