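#' Six-resource household profiles
#'
#' Computes, for every household, a numeric endowment profile over six key
#' resources governing the viability of livelihood practices:
#' agro-ecological ability, labour, financial capital, land holdings,
#' livestock holdings and social capital. Each axis is a configurable
#' expression over survey fields (see [default_resource_proxies()] for the
#' documented stand-in defaults); `market_access` (the village proxy) is
#' available inside expressions. A standardised copy (z-score over the full
#' household set, sample sd) is attached for distance computations.
#'
#' @param records Clean household table.
#' @param proxies Named list of six expression strings.
#' @return List: `raw` (data.frame `household_id` + six columns),
#'   `standardized` (same shape, mean 0 / sd 1 columns).
#' @export
resource_profile <- function(records, proxies = default_resource_proxies()) {
  env <- as.list(records)
  env$market_access <- market_access_proxy(records)
  vals <- lapply(names(proxies), function(axis) {
    expr <- tryCatch(parse(text = proxies[[axis]])[[1]],
                     error = function(e)
                       stop("invalid proxy expression for ", axis, ": ",
                            proxies[[axis]], call. = FALSE))
    v <- tryCatch(eval(expr, envir = env),
                  error = function(e)
                    stop("proxy for ", axis,
                         " references unknown field: ",
                         conditionMessage(e), call. = FALSE))
    if (!is.numeric(v) || length(v) != nrow(records)) {
      stop("proxy for ", axis, " must yield one number per household",
           call. = FALSE)
    }
    v
  })
  names(vals) <- names(proxies)
  raw <- cbind(data.frame(household_id = records$household_id,
                          stringsAsFactors = FALSE),
               as.data.frame(vals))
  zt <- z_transform(raw[, names(proxies)])
  std <- cbind(raw["household_id"], as.data.frame(zt$scaled))
  list(raw = raw, standardized = std)
}

#' Nearest resource homologues
#'
#' For every target household, finds the `k` visited positive deviants with
#' the smallest Euclidean distance in standardised six-resource space (its
#' 1st..kth "resource homologues"). Euclidean distance treats surpluses and
#' shortfalls in a resource symmetrically. Distance ties are broken by
#' ascending deviant household id; a target that is itself a visited
#' deviant matches itself at distance 0 unless `include_self = FALSE`.
#'
#' @param profiles `standardized` data.frame from [resource_profile()]
#'   (all households).
#' @param deviant_ids Ids of the visited positive deviants (at least `k`,
#'   or `k + 1` when excluding self-matches).
#' @param k Number of homologues per household (default 3).
#' @param include_self Allow self-matching for deviant targets (default
#'   `TRUE`).
#' @return Data.frame of class `pd_homologues`: `household_id`,
#'   `homologue_1..k`, `distance_1..k`; distances non-decreasing in order.
#' @export
nearest_homologues <- function(profiles, deviant_ids, k = 3,
                               include_self = TRUE) {
  axes <- setdiff(names(profiles), "household_id")
  dev_rows <- match(deviant_ids, profiles$household_id)
  if (anyNA(dev_rows)) {
    stop("deviant id(s) absent from profiles: ",
         paste(deviant_ids[is.na(dev_rows)], collapse = ", "),
         call. = FALSE)
  }
  if (length(deviant_ids) < k) {
    stop("need at least k = ", k, " visited deviants", call. = FALSE)
  }
  dm <- as.matrix(profiles[dev_rows, axes])
  # order deviants by id so which.min-style selection breaks ties by id
  id_ord <- order(deviant_ids)
  dm <- dm[id_ord, , drop = FALSE]
  dev_ids_sorted <- deviant_ids[id_ord]

  n <- nrow(profiles)
  hom <- matrix(NA_character_, n, k)
  dist <- matrix(NA_real_, n, k)
  tm <- as.matrix(profiles[, axes])
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(dm) - tm[i, ])^2))
    cand <- seq_along(d)
    if (!include_self) {
      cand <- cand[dev_ids_sorted != profiles$household_id[i]]
      if (length(cand) < k) {
        stop("fewer than k non-self deviants for household ",
             profiles$household_id[i], call. = FALSE)
      }
    }
    ord <- cand[order(d[cand])][seq_len(k)]
    hom[i, ] <- dev_ids_sorted[ord]
    dist[i, ] <- d[ord]
  }
  out <- data.frame(household_id = profiles$household_id,
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    out[[paste0("homologue_", j)]] <- hom[, j]
    out[[paste0("distance_", j)]] <- dist[, j]
  }
  class(out) <- c("pd_homologues", "data.frame")
  out
}

#' Household practice menus and practice targeting
#'
#' The practice menu of a household is the union of the uncommon
#' ("deviant") practices observed with its resource homologues. The
#' per-practice target count is the number of households whose menu
#' contains the practice — the households for which the practice is a
#' plausible, resource-compatible option. Homologues without any observed
#' practice contribute nothing.
#'
#' @param homologues Result of [nearest_homologues()].
#' @param catalog Practice catalog (see [read_practice_catalog()]).
#' @return List: `menus` (named list of practice-code vectors per
#'   household), `targeting` (data.frame practice_code,
#'   n_target_households, share).
#' @export
practice_menu <- function(homologues, catalog) {
  hom_cols <- grep("^homologue_", names(homologues), value = TRUE)
  by_holder <- split(catalog$practice_code, catalog$positive_deviant_id)
  menus <- lapply(seq_len(nrow(homologues)), function(i) {
    hs <- unlist(homologues[i, hom_cols], use.names = FALSE)
    sort(unique(unlist(by_holder[hs], use.names = FALSE)))
  })
  names(menus) <- homologues$household_id
  codes <- sort(unique(catalog$practice_code))
  counts <- vapply(codes, function(code)
    sum(vapply(menus, function(m) code %in% m, logical(1))), integer(1))
  targeting <- data.frame(
    practice_code = codes,
    n_target_households = as.integer(counts),
    share = as.numeric(counts) / nrow(homologues),
    stringsAsFactors = FALSE
  )
  rownames(targeting) <- NULL
  list(menus = menus, targeting = targeting)
}
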