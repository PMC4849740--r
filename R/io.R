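# File formats: square and long-format RDM CSVs, PNG stimuli, run
# configuration, and deterministic result bundles with a hashed manifest.
# CSV dialect is pinned: UTF-8, comma separator, dot decimal.

#' Write an RDM as a square CSV
#'
#' Header row and first column carry the stimulus ids; the undefined
#' diagonal is written as empty cells.
#'
#' @param x An [rdm].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rdm_csv <- function(x, path) {
  m <- as.matrix(x)
  ids <- stimulus_ids(x)
  chr <- matrix(as.character(m), nrow(m))
  chr[is.na(m)] <- ""
  df <- data.frame(stimulus_id = ids, chr, stringsAsFactors = FALSE)
  names(df) <- c("stimulus_id", ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a square-CSV RDM
#'
#' @param path File written by [write_rdm_csv()].
#' @param metric,strata Passed to [rdm()].
#' @return An [rdm].
#' @export
read_rdm_csv <- function(path, metric = "external", strata = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  m <- matrix(as.numeric(m), nrow(m), dimnames = list(ids, ids))
  rdm(m, stimulus_ids = ids, metric = metric, strata = strata)
}

#' Write a participant RDM stack as long-format CSV
#'
#' Columns: `participant`, `row_item`, `col_item`, `value`; both triangles
#' are written, the diagonal is omitted.
#'
#' @param stack List of matched [rdm]s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_behavior_rdms <- function(stack, path) {
  rows <- lapply(seq_along(stack), function(p) {
    m <- as.matrix(stack[[p]])
    ids <- stimulus_ids(stack[[p]])
    idx <- which(row(m) != col(m), arr.ind = TRUE)
    data.frame(participant = p, row_item = ids[idx[, 1]],
               col_item = ids[idx[, 2]], value = m[idx],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a participant RDM stack
#'
#' Accepts a long-format CSV (`participant, row_item, col_item, value`) or a
#' character vector of per-participant square CSVs. Validates symmetry to
#' 1e-9 and completeness; a missing diagonal is expected.
#'
#' @param path Long-format CSV path, or vector of square-CSV paths.
#' @return List of [rdm]s, one per participant.
#' @export
read_behavior_rdms <- function(path) {
  if (length(path) > 1) {
    return(lapply(path, read_rdm_csv))
  }
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE)
  need <- c("participant", "row_item", "col_item", "value")
  if (!all(need %in% names(df))) {
    stop("long-format stack needs columns: ", paste(need, collapse = ", "))
  }
  ids <- sort(unique(c(df$row_item, df$col_item)))
  n <- length(ids)
  lapply(sort(unique(df$participant)), function(p) {
    sub <- df[df$participant == p, ]
    m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    m[cbind(match(sub$row_item, ids), match(sub$col_item, ids))] <- sub$value
    off <- which(row(m) != col(m) & is.na(m), arr.ind = TRUE)
    if (nrow(off)) {
      stop("participant ", p, " is missing pair(s): ",
           paste(ids[off[, 1]], ids[off[, 2]], sep = "~", collapse = ", "))
    }
    asym <- abs(m - t(m)); diag(asym) <- 0
    if (max(asym) > 1e-9) {
      w <- sort(which(asym == max(asym), arr.ind = TRUE)[1, ])
      stop("participant ", p, " asymmetric at (", ids[w[1]], ", ",
           ids[w[2]], "): ", m[w[1], w[2]], " vs ", m[w[2], w[1]])
    }
    rdm(m, stimulus_ids = ids, metric = "external")
  })
}

#' Save a stimulus as an 8-bit PNG
#'
#' @param stimulus An [image_stimulus].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_stimulus_png <- function(stimulus, path) {
  png::writePNG(stimulus$pixels, path)
  invisible(path)
}

#' Run configuration
#'
#' Resolves analysis settings from a JSON file or a named list, filling
#' defaults; every run writes its resolved configuration beside its
#' outputs.
#'
#' @param config Path to a JSON config or a named list.
#' @return List with at least `seed`, `n_iter` (default 1000, >= 1),
#'   `metric`, `stratified`, `out_dir`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(seed = 1L, n_iter = 1000L, metric = "correlation",
                   stratified = FALSE, out_dir = "results")
  cfg <- utils::modifyList(defaults, config)
  cfg$n_iter <- as.integer(cfg$n_iter)
  if (is.na(cfg$n_iter) || cfg$n_iter < 1) stop("n_iter must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# write one result object under a deterministic file name; returns the name
.write_result_item <- function(name, x, out_dir) {
  if (inherits(x, "rdm")) {
    f <- paste0(name, ".csv"); write_rdm_csv(x, file.path(out_dir, f))
  } else if (is.data.frame(x)) {
    f <- paste0(name, ".csv")
    utils::write.csv(x, file.path(out_dir, f), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  } else if (is.matrix(x)) {
    f <- paste0(name, ".csv")
    utils::write.csv(as.data.frame(x), file.path(out_dir, f),
                     row.names = !is.null(rownames(x)), quote = FALSE,
                     fileEncoding = "UTF-8")
  } else if (inherits(x, "bootstrap_result")) {
    f <- paste0(name, ".json")
    jsonlite::write_json(list(point = x$point, ci = c(x$ci_low, x$ci_high),
                              n_iter = x$n_iter, seed = x$seed),
                         file.path(out_dir, f), auto_unbox = TRUE,
                         digits = NA)
  } else {
    f <- paste0(name, ".json")
    jsonlite::write_json(x, file.path(out_dir, f), auto_unbox = TRUE,
                         digits = NA, force = TRUE, null = "null")
  }
  f
}

#' Write a result bundle with a hashed manifest
#'
#' Serializes a named list of results (RDMs and data frames as CSV,
#' everything else as JSON) into `out_dir` under deterministic file names,
#' then writes `manifest.json` listing every artifact with its MD5 content
#' hash plus the package version; running the same configuration twice
#' yields hash-identical manifests.
#'
#' @param results Named list of result objects.
#' @param out_dir Output directory (created if needed).
#' @param config Optional resolved [run_config()] to store alongside.
#' @return The manifest, invisibly.
#' @export
write_result_bundle <- function(results, out_dir, config = NULL) {
  stopifnot(is.list(results), !is.null(names(results)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(results)) {
    files[nm] <- .write_result_item(nm, results[[nm]], out_dir)
  }
  if (!is.null(config)) {
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    files["config"] <- "config.json"
  }
  hashes <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    artifacts = stats::setNames(as.list(unname(hashes)), unname(files)),
    package_version = as.character(utils::packageVersion("shapersa")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
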