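# File formats: wide/long response CSV, item parameter CSV/JSON, design and
# truth-bundle JSON. Wide CSV is canonical; "NA" is the only missing token;
# category codes are 0-based integers.

#' Read and write response matrices
#'
#' Wide format: one row per person, first column \code{person_id}, one column
#' per item, "NA" for unadministered cells. Long format: columns
#' \code{person_id}, \code{item_id}, \code{response}, observed cells only.
#'
#' @param x integer response matrix (persons x items, dimnames used as ids).
#' @param path CSV file path.
#' @param format "wide" or "long".
#' @return \code{read_responses} returns an integer matrix with person ids
#'   as rownames and item ids as colnames.
#' @export
write_responses <- function(x, path, format = c("wide", "long")) {
  format <- match.arg(format)
  pid <- rownames(x); if (is.null(pid)) pid <- sprintf("p%04d", seq_len(nrow(x)))
  iid <- colnames(x); if (is.null(iid)) iid <- sprintf("i%03d", seq_len(ncol(x)))
  if (format == "wide") {
    df <- data.frame(person_id = pid, x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE, na = "NA")
  } else {
    obs <- which(!is.na(x), arr.ind = TRUE)
    df <- data.frame(person_id = pid[obs[, 1]], item_id = iid[obs[, 2]],
                     response = x[obs], stringsAsFactors = FALSE)
    df <- df[order(df$person_id, df$item_id), ]
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- tryCatch(read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (format == "wide") {
    if (names(df)[1] != "person_id")
      stop(path, ": wide response CSV must start with a person_id column")
    X <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(X) <- "integer"
    rownames(X) <- df$person_id
    X
  } else {
    need <- c("person_id", "item_id", "response")
    if (!all(need %in% names(df)))
      stop(path, ": long response CSV needs columns ",
           paste(need, collapse = ", "))
    pid <- sort(unique(df$person_id)); iid <- sort(unique(df$item_id))
    X <- matrix(NA_integer_, length(pid), length(iid),
                dimnames = list(pid, iid))
    X[cbind(match(df$person_id, pid), match(df$item_id, iid))] <-
      as.integer(df$response)
    X
  }
}

#' Read and write item parameter tables
#'
#' The on-disk dialect has columns \code{item_id}, \code{item_type},
#' \code{K}, \code{domain}, \code{a0}, \code{a1..aD} (the specific slope in
#' the item's own domain column, zero elsewhere), and \code{b1..b_(Kmax-1)}.
#' In memory the single specific slope is held in column \code{av} alongside
#' \code{domain}.
#'
#' @param items internal item parameter table.
#' @param path CSV file path.
#' @param n_domains number of specific-slope columns to write.
#' @param model model tag used for validation on read.
#' @export
write_item_params <- function(items, path, n_domains = 5L) {
  ext <- item_params_external(items, n_domains)
  write.csv(ext, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_item_params
#' @export
read_item_params <- function(path, model = c("FIBF", "UIRT", "MIRT")) {
  model <- match.arg(model)
  ext <- read.csv(path, stringsAsFactors = FALSE)
  item_params_internal(ext, model)
}

item_params_external <- function(items, n_domains = 5L) {
  A <- matrix(0, nrow(items), n_domains,
              dimnames = list(NULL, paste0("a", seq_len(n_domains))))
  A[cbind(seq_len(nrow(items)), items$domain)] <- items$av
  cbind(items[c("item_id", "item_type", "K", "domain", "a0")],
        as.data.frame(A), as.data.frame(intercept_matrix(items)))
}

item_params_internal <- function(ext, model) {
  acols <- grep("^a[1-9][0-9]*$", names(ext), value = TRUE)
  A <- as.matrix(ext[, acols, drop = FALSE])
  nz <- rowSums(A != 0)
  if (model != "UIRT" && any(nz > 1))
    stop("each item must have exactly one nonzero specific slope")
  av <- A[cbind(seq_len(nrow(ext)), ext$domain)]
  out <- cbind(ext[c("item_id", "item_type", "K", "domain", "a0")],
               data.frame(av = av),
               ext[grep("^b[0-9]+$", names(ext), value = TRUE)])
  attr(out, "model") <- model
  validate_item_params(out, model, n_domains = ncol(A))
  out
}

#' JSON round-trip of item parameter tables
#' @inheritParams write_item_params
#' @export
write_item_params_json <- function(items, path, n_domains = 5L) {
  jsonlite::write_json(item_params_external(items, n_domains), path,
                       dataframe = "rows", na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_item_params_json
#' @export
read_item_params_json <- function(path, model = c("FIBF", "UIRT", "MIRT")) {
  model <- match.arg(model)
  ext <- jsonlite::fromJSON(path)
  item_params_internal(ext, model)
}

#' Read and write test designs as JSON
#' @param design a \code{\link{build_design}} object.
#' @param path JSON file path.
#' @export
write_design <- function(design, path) {
  jsonlite::write_json(
    list(n_booklets = design$n_booklets, M = design$M, N = design$N,
         n_domains = design$n_domains, items = design$items,
         booklet_items = design$booklet_items,
         person_booklet = design$person_booklet),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- jsonlite::fromJSON(path, simplifyMatrix = FALSE)
  structure(list(n_booklets = as.integer(d$n_booklets),
                 M = as.integer(d$M), N = as.integer(d$N),
                 n_domains = as.integer(d$n_domains),
                 items = as.data.frame(d$items),
                 booklet_items = lapply(d$booklet_items, as.integer),
                 person_booklet = as.integer(d$person_booklet)),
            class = "test_design")
}

#' Write / read a simulation truth bundle
#'
#' Serialises an \code{\link{sim_study}} object to a directory of plain-text
#' files (design JSON, true item parameter CSV, ability CSV, latent
#' covariance CSV for MIRT, wide response CSV, meta JSON) and reads it back
#' losslessly.
#'
#' @param sim an \code{irt_sim} object.
#' @param dir output directory (created if needed).
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_design(sim$design, file.path(dir, "design.json"))
  write_item_params(sim$items, file.path(dir, "items_true.csv"),
                    sim$design$n_domains)
  ab <- data.frame(person_id = rownames(sim$responses), sim$theta)
  names(ab)[-1] <- paste0("theta", seq_len(ncol(sim$theta)))
  write.csv(ab, file.path(dir, "abilities.csv"), row.names = FALSE)
  if (!is.null(sim$Sigma))
    write.csv(sim$Sigma, file.path(dir, "sigma_theta.csv"),
              row.names = FALSE)
  write_responses(sim$responses, file.path(dir, "responses.csv"))
  jsonlite::write_json(list(model = sim$model, seed = sim$seed,
                            format_version = "1"),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  design <- read_design(file.path(dir, "design.json"))
  items <- read_item_params(file.path(dir, "items_true.csv"), meta$model)
  ab <- read.csv(file.path(dir, "abilities.csv"), stringsAsFactors = FALSE)
  theta <- as.matrix(ab[, -1, drop = FALSE])
  dimnames(theta) <- NULL
  Sigma <- NULL
  sp <- file.path(dir, "sigma_theta.csv")
  if (file.exists(sp)) Sigma <- unname(as.matrix(read.csv(sp)))
  X <- read_responses(file.path(dir, "responses.csv"))
  structure(list(model = meta$model, design = design, items = items,
                 theta = theta, Sigma = Sigma, responses = X,
                 seed = as.integer(meta$seed)),
            class = "irt_sim")
}
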