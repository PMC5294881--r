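#' Read or write an adaptive design file
#'
#' Designs are exchanged as JSON or CSV. The JSON layout is a flat object
#' with the scalar fields plus a `stages` array, one element per
#' continuation value:
#' `{"pi0":0.3, "pi1":0.5, "alpha":0.05, "beta":0.1, "n1":22,
#'   "r1_futility":f, "r1_efficacy":e, "stages":[{"x1":k,"n2":m,"r":c},...]}`.
#' The CSV layout carries the scalar fields as a `# key: value` header block
#' followed by columns `x1, n2, r`. Both round-trip losslessly.
#'
#' @param path File path; the format is chosen by extension (`.json` or
#'   `.csv`) unless `format` is given.
#' @param format `"json"` or `"csv"`; default inferred from `path`.
#' @return `read_design()` returns an [adaptive_design()];
#'   `write_design()` returns `path` invisibly.
#' @examples
#' toy <- adaptive_design(2, 0, 2, n2 = 2, r = 2, pi0 = 0.5)
#' f <- tempfile(fileext = ".json")
#' write_design(toy, f)
#' identical(read_design(f), toy)
#' @export
read_design <- function(path, format = NULL) {
  format <- format %||% infer_format(path)
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    stages <- raw$stages
    if (is.null(stages) || nrow(stages) == 0) {
      rlang::abort("design file has no continuation stages")
    }
    stages <- stages[order(stages$x1), , drop = FALSE]
    design <- adaptive_design(
      n1 = raw$n1, r1_futility = raw$r1_futility, r1_efficacy = raw$r1_efficacy,
      n2 = stats::setNames(stages$n2, stages$x1),
      r = stats::setNames(stages$r, stages$x1),
      pi0 = raw$pi0, pi1 = raw$pi1, alpha = raw$alpha, beta = raw$beta
    )
  } else {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    kv <- list()
    for (h in hdr) {
      m <- regmatches(h, regexec("^#\\s*([a-z0-9_]+)\\s*:\\s*(.+)$", h))[[1]]
      if (length(m) == 3) kv[[m[2]]] <- as.numeric(m[3])
    }
    need <- c("n1", "r1_futility", "r1_efficacy", "pi0", "pi1", "alpha", "beta")
    miss <- setdiff(need, names(kv))
    if (length(miss) > 0) {
      rlang::abort(sprintf("design CSV header is missing: %s", paste(miss, collapse = ", ")))
    }
    tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
    tab <- tab[order(tab$x1), , drop = FALSE]
    design <- adaptive_design(
      n1 = kv$n1, r1_futility = kv$r1_futility, r1_efficacy = kv$r1_efficacy,
      n2 = stats::setNames(tab$n2, tab$x1),
      r = stats::setNames(tab$r, tab$x1),
      pi0 = kv$pi0, pi1 = kv$pi1, alpha = kv$alpha, beta = kv$beta
    )
  }
  stop_if_invalid(design)
  design
}

#' @rdname read_design
#' @param design An [adaptive_design()] to serialise.
#' @export
write_design <- function(design, path, format = NULL) {
  stop_if_invalid(design)
  format <- format %||% infer_format(path)
  cont <- continuation_values(design)
  if (format == "json") {
    obj <- list(
      pi0 = design$pi0, pi1 = design$pi1,
      alpha = design$alpha, beta = design$beta,
      n1 = design$n1,
      r1_futility = design$r1_futility, r1_efficacy = design$r1_efficacy,
      stages = data.frame(
        x1 = cont, n2 = as.integer(design$n2), r = as.integer(design$r)
      )
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    hdr <- sprintf(
      "# %s: %s",
      c("n1", "r1_futility", "r1_efficacy", "pi0", "pi1", "alpha", "beta"),
      vapply(
        design[c("n1", "r1_futility", "r1_efficacy", "pi0", "pi1", "alpha", "beta")],
        function(x) format(x, digits = 17), character(1)
      )
    )
    body <- c(
      "x1,n2,r",
      sprintf("%d,%d,%d", cont, as.integer(design$n2), as.integer(design$r))
    )
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "csv")) return(ext)
  rlang::abort(sprintf("cannot infer design format from '%s'; pass format=", path))
}
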