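#' Build a linked-booklet incomplete block test design
#'
#' Constructs the cyclic chain design used for incomplete test
#' administration: the item pool is split into \code{n_booklets} blocks and
#' booklet i is the union of block i and block i+1 (mod n_booklets), so each
#' item appears in exactly two booklets and adjacent booklets share one full
#' block. Persons are allocated to booklets round-robin, as evenly as
#' possible. At the default configuration (6 booklets of 20 items, 12
#' dichotomous + 8 three-category each, 2000 persons) this yields 60 items,
#' every booklet answered by at least 300 persons, and every item answered by
#' at least 600.
#'
#' Content domains 1..\code{n_domains} are assigned to the item pool either
#' in contiguous blocks of M/D items (\code{domain_layout = "blocked"}, the
#' default, so each booklet concentrates on few domains and every person
#' answers many items of each domain they see) or cyclically
#' (\code{"cyclic"}, every booklet measures all domains with few items
#' each). The layout changes how well the domain-specific factors are
#' separated per person and therefore how sharply the bifactor model is
#' distinguished from its competitors.
#'
#' @param n_booklets number of booklets (= number of blocks).
#' @param items_per_booklet items per booklet (even; two blocks of half this).
#' @param n_dich,n_poly dichotomous / polytomous items per booklet (each even,
#'   summing to \code{items_per_booklet}).
#' @param n_persons number of examinees.
#' @param n_domains number of content domains.
#' @param n_cat_poly categories of the polytomous items (default 3).
#' @param domain_layout "blocked" (contiguous runs of M/D items per domain)
#'   or "cyclic" (domains rotate item by item).
#' @return object of class \code{test_design}: item table (\code{items}),
#'   \code{booklet_items} (list of item indices), \code{person_booklet}
#'   (integer vector), and the sizes.
#' @examples
#' d <- build_design()
#' d$M                                   # 60
#' table(tabulate(unlist(d$booklet_items), d$M))  # every item in 2 booklets
#' @export
build_design <- function(n_booklets = 6L, items_per_booklet = 20L,
                         n_dich = 12L, n_poly = 8L, n_persons = 2000L,
                         n_domains = 5L, n_cat_poly = 3L,
                         domain_layout = c("blocked", "cyclic")) {
  domain_layout <- match.arg(domain_layout)
  n_dich <- as.integer(n_dich); n_poly <- as.integer(n_poly)
  n_persons <- as.integer(n_persons); n_domains <- as.integer(n_domains)
  n_booklets <- as.integer(n_booklets)
  items_per_booklet <- as.integer(items_per_booklet)
  if (n_booklets < 2) stop("need at least 2 booklets")
  if (n_dich + n_poly != items_per_booklet)
    stop("n_dich + n_poly must equal items_per_booklet")
  if (items_per_booklet %% 2L || n_dich %% 2L || n_poly %% 2L)
    stop("items_per_booklet, n_dich and n_poly must all be even ",
         "(each booklet is two half-booklet blocks)")
  block_size <- items_per_booklet %/% 2L
  M <- n_booklets * block_size
  if (n_booklets * items_per_booklet != 2L * M)  # structural identity
    stop("inconsistent item counts")

  bd <- n_dich %/% 2L  # dichotomous items per block
  item_type <- rep(rep(c("dichotomous", "graded"),
                       c(bd, block_size - bd)), n_booklets)
  block <- rep(seq_len(n_booklets), each = block_size)
  items <- data.frame(
    item_id = sprintf("i%03d", seq_len(M)),
    block = block,
    item_type = item_type,
    K = ifelse(item_type == "dichotomous", 2L, as.integer(n_cat_poly)),
    domain = if (domain_layout == "cyclic")
        ((seq_len(M) - 1L) %% n_domains) + 1L
      else pmin(((seq_len(M) - 1L) * n_domains) %/% M + 1L, n_domains),
    stringsAsFactors = FALSE
  )
  booklet_items <- lapply(seq_len(n_booklets), function(i) {
    blocks <- c(i, if (i == n_booklets) 1L else i + 1L)
    which(block %in% blocks)
  })
  person_booklet <- ((seq_len(n_persons) - 1L) %% n_booklets) + 1L
  structure(list(n_booklets = n_booklets, M = M, N = as.integer(n_persons),
                 n_domains = as.integer(n_domains), items = items,
                 booklet_items = booklet_items,
                 person_booklet = person_booklet),
            class = "test_design")
}

#' @export
print.test_design <- function(x, ...) {
  cat("Linked-booklet test design:", x$n_booklets, "booklets,",
      x$M, "items,", x$N, "persons\n")
  cat("  items per booklet:", length(x$booklet_items[[1]]),
      sprintf("(%d dichotomous, %d graded)",
              sum(x$items$item_type[x$booklet_items[[1]]] == "dichotomous"),
              sum(x$items$item_type[x$booklet_items[[1]]] == "graded")), "\n")
  cat("  domains:", x$n_domains,
      "| min respondents per item:", min(item_respondents(x)), "\n")
  invisible(x)
}

# respondents answering each item
item_respondents <- function(design) {
  nb <- tabulate(design$person_booklet, design$n_booklets)
  vapply(seq_len(design$M), function(j) {
    bks <- which(vapply(design$booklet_items, function(b) j %in% b, logical(1)))
    sum(nb[bks])
  }, numeric(1))
}

# logical N x M incidence: cell observed iff item in person's booklet
design_incidence <- function(design) {
  inc <- matrix(FALSE, design$N, design$M)
  for (b in seq_len(design$n_booklets)) {
    rows <- which(design$person_booklet == b)
    inc[rows, design$booklet_items[[b]]] <- TRUE
  }
  inc
}
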