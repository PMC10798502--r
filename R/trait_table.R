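#' Plot-level trait tables for balanced multi-environment trials
#'
#' A `trait_table` is a long-format data frame of plot observations with
#' columns `genotype`, `environment`, `replicate`, `trait` and `value`.
#' It is the single input currency of the pipeline: one row per plot value
#' of one trait for one genotype in one environment (typically a year) and
#' one replicate block of an RCBD.
#'
#' Genotype, environment and trait labels are opaque strings kept in
#' first-appearance order; year labels such as `"2019-20"` are never parsed
#' as dates. Replicates are small positive integers.
#'
#' @param x A data frame with the five canonical columns (extra columns are
#'   dropped with a warning).
#' @param require_balance If `TRUE` (default), fail unless every
#'   (genotype, environment, replicate, trait) combination is present
#'   exactly once. Downstream ANOVA always requires balance.
#' @return An object of class `trait_table`: the validated data frame with
#'   attributes `genotypes`, `environments`, `traits` (first-appearance
#'   order) and `replicates` (sorted unique replicate ids).
#' @examples
#' df <- expand.grid(genotype = c("G1", "G2"), environment = "E1",
#'                   replicate = 1:2, trait = "PH",
#'                   stringsAsFactors = FALSE)
#' df$value <- c(10, 12, 11, 13)
#' tt <- trait_table(df)
#' genotypes(tt)
#' @export
trait_table <- function(x, require_balance = TRUE) {
  need <- c("genotype", "environment", "replicate", "trait", "value")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(x), need)
  if (length(extra)) {
    warning("dropping extra column(s): ", paste(extra, collapse = ", "))
  }
  x <- as.data.frame(x)[need]
  x$genotype <- as.character(x$genotype)
  x$environment <- as.character(x$environment)
  x$trait <- as.character(x$trait)
  rep_num <- suppressWarnings(as.numeric(x$replicate))
  if (anyNA(rep_num) || any(rep_num != round(rep_num)) || any(rep_num < 1)) {
    stop("replicate must be an integer >= 1")
  }
  x$replicate <- as.integer(rep_num)
  x$value <- as.numeric(x$value)
  if (any(!is.finite(x$value))) {
    bad <- which(!is.finite(x$value))
    stop("non-finite value(s) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  key <- paste(x$genotype, x$environment, x$replicate, x$trait, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf(
      "duplicate plot record: genotype=%s environment=%s replicate=%d trait=%s",
      dup$genotype, dup$environment, dup$replicate, dup$trait))
  }
  out <- structure(x,
                   genotypes = unique(x$genotype),
                   environments = unique(x$environment),
                   traits = unique(x$trait),
                   replicates = sort(unique(x$replicate)),
                   class = c("trait_table", "data.frame"))
  if (require_balance) {
    miss <- missing_cells(out)
    if (nrow(miss)) {
      stop("unbalanced table: ", nrow(miss), " missing cell(s), first: ",
           paste(unlist(miss[1L, ]), collapse = "/"))
    }
  }
  out
}

#' @rdname trait_table
#' @export
genotypes <- function(x) attr(x, "genotypes")

#' @rdname trait_table
#' @export
environments <- function(x) attr(x, "environments")

#' @rdname trait_table
#' @export
traits <- function(x) attr(x, "traits")

#' @rdname trait_table
#' @export
replicates <- function(x) attr(x, "replicates")

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf(
    "trait_table: %d records | %d genotypes x %d environments x %d replicates x %d traits\n",
    nrow(x), length(genotypes(x)), length(environments(x)),
    length(replicates(x)), length(traits(x))))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Enumerate missing design cells
#'
#' Lists every (genotype, environment, replicate, trait) combination of the
#' full cross that has no record — empty for a balanced table.
#'
#' @param x A `trait_table` (or plain data frame with the five columns).
#' @return Data frame of missing combinations (zero rows when balanced).
#' @export
missing_cells <- function(x) {
  full <- expand.grid(genotype = unique(x$genotype),
                      environment = unique(x$environment),
                      replicate = sort(unique(x$replicate)),
                      trait = unique(x$trait),
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  have <- paste(x$genotype, x$environment, x$replicate, x$trait, sep = "\r")
  want <- paste(full$genotype, full$environment, full$replicate, full$trait,
                sep = "\r")
  full[!(want %in% have), , drop = FALSE]
}

#' Read a long-format trait table from CSV/TSV
#'
#' @param path Path to a delimited text file with a header row.
#' @param columns Named character vector mapping canonical names
#'   (`genotype`, `environment`, `replicate`, `trait`, `value`) to the
#'   file's column names; defaults to the canonical names themselves.
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @param require_balance Passed to [trait_table()].
#' @return A validated [trait_table].
#' @export
read_trait_table <- function(path, columns = NULL, sep = ",",
                             require_balance = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  map <- c(genotype = "genotype", environment = "environment",
           replicate = "replicate", trait = "trait", value = "value")
  if (!is.null(columns)) map[names(columns)] <- columns
  missing_cols <- map[!(map %in% names(raw))]
  if (length(missing_cols)) {
    stop("file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(genotype = raw[[map[["genotype"]]]],
                   environment = raw[[map[["environment"]]]],
                   replicate = raw[[map[["replicate"]]]],
                   trait = raw[[map[["trait"]]]],
                   value = raw[[map[["value"]]]],
                   stringsAsFactors = FALSE)
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val)) {
    bad <- which(is.na(val))[1L]
    stop(sprintf("non-numeric value %s at data row %d", df$value[bad], bad))
  }
  df$value <- val
  trait_table(df, require_balance = require_balance)
}

#' Write a trait table back to CSV/TSV
#'
#' Inverse of [read_trait_table()]: `read_trait_table(write_trait_table(x, f))`
#' reproduces the same records.
#'
#' @param x A `trait_table`.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path, sep = ",") {
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Import a wide one-trait-per-column matrix
#'
#' Convenience importer for the common wide layout (one row per plot,
#' genotype/environment/replicate columns plus one column per trait);
#' normalized to the canonical long format on read.
#'
#' @param path Delimited file with header.
#' @param id_cols Names of the genotype, environment and replicate columns.
#' @param sep Field separator.
#' @inheritParams trait_table
#' @return A [trait_table].
#' @export
read_wide_trait_table <- function(path,
                                  id_cols = c("genotype", "environment",
                                              "replicate"),
                                  sep = ",", require_balance = TRUE) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(id_cols %in% names(raw))) {
    stop("file lacks id column(s): ",
         paste(setdiff(id_cols, names(raw)), collapse = ", "))
  }
  trait_cols <- setdiff(names(raw), id_cols)
  if (!length(trait_cols)) stop("no trait columns found")
  long <- do.call(rbind, lapply(trait_cols, function(tr) {
    data.frame(genotype = as.character(raw[[id_cols[1L]]]),
               environment = as.character(raw[[id_cols[2L]]]),
               replicate = raw[[id_cols[3L]]],
               trait = tr,
               value = as.numeric(raw[[tr]]),
               stringsAsFactors = FALSE)
  }))
  trait_table(long, require_balance = require_balance)
}

#' Genotype-by-environment mean matrix for one trait
#'
#' Averages plot values over replicates, giving the genotype x environment
#' mean table that feeds correlation, regression and GAI stages. Overall
#' (across-environment) genotype means are attached as attribute
#' `"genotype_means"`.
#'
#' @param x A balanced `trait_table`.
#' @param trait Trait identifier present in `x`.
#' @return Numeric matrix, genotypes in rows (table order), environments in
#'   columns.
#' @export
genotype_env_means <- function(x, trait) {
  if (!trait %in% traits(x)) stop("unknown trait: ", trait)
  d <- x[x$trait == trait, , drop = FALSE]
  g <- factor(d$genotype, levels = genotypes(x))
  e <- factor(d$environment, levels = environments(x))
  m <- tapply(d$value, list(g, e), mean)
  m <- matrix(m, nrow = nlevels(g), ncol = nlevels(e),
              dimnames = list(levels(g), levels(e)))
  attr(m, "genotype_means") <- tapply(d$value, g, mean)[levels(g)]
  m
}

# internal: slice one trait/environment into a genotype x replicate matrix
.slice_matrix <- function(x, trait, environment) {
  d <- x[x$trait == trait & x$environment == environment, , drop = FALSE]
  if (!nrow(d)) stop("no records for trait ", trait,
                     " in environment ", environment)
  g <- factor(d$genotype, levels = unique(d$genotype))
  r <- factor(d$replicate, levels = sort(unique(d$replicate)))
  m <- tapply(d$value, list(g, r), function(v) {
    if (length(v) != 1L) stop("duplicate plot in slice")
    v
  })
  m <- matrix(m, nrow = nlevels(g), ncol = nlevels(r),
              dimnames = list(levels(g), levels(r)))
  if (anyNA(m)) stop("unbalanced slice for trait ", trait,
                     " in environment ", environment)
  m
}
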