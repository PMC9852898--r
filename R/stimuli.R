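#' Synthetic food-image table
#'
#' Builds a synthetic inventory of food images with nutrient-warning-label
#' (NWL) counts and per-100 g nutrient values. It is a stand-in for a real
#' image database: ids, categories and nutrients are generated, with nutrient
#' levels loosely increasing in the NWL count so the table is internally
#' coherent. The default stratum sizes (0 NWL: 23, 1 NWL: 18, 2 NWL: 23,
#' 3 NWL: 30; 94 images in total) match the pooled per-context strata used by
#' [default_strata_spec()].
#'
#' @param n_per_nwl Named or ordered integer vector of pool sizes for NWL
#'   counts 0..3.
#' @param seed Seed for the generated categories/nutrients.
#' @return Data frame with columns `image_id`, `category`, `kcal`,
#'   `sat_fat_g`, `sugar_g`, `sodium_mg`, `nwl_count`.
#' @export
synthetic_image_table <- function(n_per_nwl = c(23L, 18L, 23L, 30L),
                                  seed = 20230106L) {
  stopifnot(length(n_per_nwl) == 4L, all(n_per_nwl >= 0))
  cats <- c("fruit", "vegetables", "prepared meals", "dessert treats",
            "snacks", "cake", "pastries", "bread", "pasta", "soups stews")
  with_seed(seed, {
    rows <- lapply(0:3, function(k) {
      n <- n_per_nwl[k + 1L]
      if (n == 0L) return(NULL)
      data.frame(
        image_id = sprintf("img%03d_nwl%d", seq_len(n), k),
        category = sample(cats, n, replace = TRUE),
        kcal = round(runif(n, 40, 180) + 110 * k),
        sat_fat_g = round(runif(n, 0.1, 2) + 2.2 * k, 1),
        sugar_g = round(runif(n, 1, 8) + 6 * k, 1),
        sodium_mg = round(runif(n, 5, 120) + 160 * k),
        nwl_count = k,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Default per-context stratum specification
#'
#' Number of images per NWL count assigned to each eating context:
#' health 32 (8/6/8/10), typical 29 (7/6/7/9), unrestricted 33 (8/6/8/11).
#'
#' @return Named list of integer vectors (NWL counts 0..3).
#' @export
default_strata_spec <- function() {
  list(healthy      = c(8L, 6L, 8L, 10L),
       typical      = c(7L, 6L, 7L, 9L),
       unrestricted = c(8L, 6L, 8L, 11L))
}

#' Build per-context image inventories by stratified allocation
#'
#' Partitions an image pool into one inventory per eating context so that
#' each context receives exactly the requested number of images per NWL
#' stratum and no image is shared between contexts.
#'
#' @param image_table Data frame as returned by [synthetic_image_table()]
#'   (columns `image_id`, `nwl_count` required).
#' @param strata_spec Named list of per-context integer vectors (NWL 0..3);
#'   defaults to [default_strata_spec()].
#' @param seed Seed controlling the random allocation.
#' @return Named list of `context_inventory` objects, each with fields
#'   `context`, `images` (data frame) and `strata_counts`.
#' @examples
#' inv <- build_inventories(synthetic_image_table())
#' vapply(inv, function(x) nrow(x$images), integer(1))
#' @export
build_inventories <- function(image_table, strata_spec = default_strata_spec(),
                              seed = 1L) {
  stopifnot(all(c("image_id", "nwl_count") %in% names(image_table)))
  if (anyDuplicated(image_table$image_id))
    stop("image_table contains duplicated image ids", call. = FALSE)
  need <- Reduce(`+`, strata_spec)
  have <- vapply(0:3, function(k) sum(image_table$nwl_count == k), integer(1))
  short <- which(have < need)
  if (length(short)) {
    k <- short[1] - 1L
    stop(sprintf(
      "insufficient images in NWL stratum %d: need %d, have %d (short by %d)",
      k, need[short[1]], have[short[1]], need[short[1]] - have[short[1]]),
      call. = FALSE)
  }
  with_seed(seed, {
    pools <- lapply(0:3, function(k) {
      ids <- image_table$image_id[image_table$nwl_count == k]
      sample(ids, length(ids))
    })
    out <- list()
    for (ctx in names(strata_spec)) {
      counts <- strata_spec[[ctx]]
      ids <- character(0)
      for (k in 0:3) {
        take <- counts[k + 1L]
        if (take > 0L) {
          ids <- c(ids, pools[[k + 1L]][seq_len(take)])
          pools[[k + 1L]] <- pools[[k + 1L]][-seq_len(take)]
        }
      }
      imgs <- image_table[match(ids, image_table$image_id), ]
      rownames(imgs) <- NULL
      out[[ctx]] <- structure(
        list(context = ctx, images = imgs,
             strata_counts = stats::setNames(counts, 0:3)),
        class = "context_inventory")
    }
    out
  })
}

#' @export
print.context_inventory <- function(x, ...) {
  cat(sprintf("Context '%s': %d images (NWL 0..3: %s)\n", x$context,
              nrow(x$images), paste(x$strata_counts, collapse = "/")))
  invisible(x)
}

# the six unordered NWL-count combinations; every pair has distinct counts so
# each trial has a well-defined healthier option
nwl_combos <- function() {
  list(c(0L, 1L), c(0L, 2L), c(0L, 3L), c(1L, 2L), c(1L, 3L), c(2L, 3L))
}

#' Generate a constrained pseudo-random pair sequence for one context
#'
#' Produces `6 * pairs_per_combo` trials honoring the three design rules:
#' (1) exactly `pairs_per_combo` pairs per NWL-count combination;
#' (2) any image skips at least two pairs before reappearing;
#' (3) no NWL count occupies the same side for more than 3 consecutive pairs.
#'
#' Construction is sequential and constraint-aware: at each position a
#' combination is drawn with probability proportional to its remaining quota,
#' images are drawn from the least-used eligible images of each stratum
#' (usage balancing keeps rule 2 feasible and image exposure even), and the
#' side assignment is chosen to respect rule 3. If a position admits no legal
#' placement the whole sequence restarts, up to `max_retries` restarts.
#'
#' @param inventory A `context_inventory` from [build_inventories()].
#' @param pairs_per_combo Pairs per NWL combination (default 15, giving the
#'   90-trial block of the study design).
#' @param max_retries Maximum sequence restarts before failing.
#' @return Data frame of trial specs: `position`, `left_image`,
#'   `right_image`, `nwl_left`, `nwl_right`, `combo`, `context`.
#' @examples
#' inv <- build_inventories(synthetic_image_table())
#' set.seed(7)
#' seq90 <- generate_pair_sequence(inv$healthy)
#' nrow(seq90)
#' @export
generate_pair_sequence <- function(inventory, pairs_per_combo = 15L,
                                   max_retries = 1000L) {
  stopifnot(inherits(inventory, "context_inventory"), pairs_per_combo >= 1)
  strata <- lapply(0:3, function(k)
    inventory$images$image_id[inventory$images$nwl_count == k])
  combos <- nwl_combos()
  for (cb in combos) {
    for (k in cb) if (length(strata[[k + 1L]]) < 1L)
      stop(sprintf("stratum %d is empty; sequence infeasible", k),
           call. = FALSE)
  }
  n_total <- 6L * pairs_per_combo

  for (attempt in seq_len(max_retries)) {
    quota <- rep(pairs_per_combo, 6L)
    usage <- lapply(strata, function(ids)
      stats::setNames(integer(length(ids)), ids))
    recent <- character(0)            # images used in the previous 2 pairs
    run_val <- c(left = NA_integer_, right = NA_integer_)
    run_len <- c(left = 0L, right = 0L)
    left_img <- character(n_total); right_img <- character(n_total)
    nwl_l <- integer(n_total); nwl_r <- integer(n_total)
    combo_ix <- integer(n_total)
    ok <- TRUE

    for (pos in seq_len(n_total)) {
      open <- which(quota > 0L)
      order_try <- if (length(open) == 1L) open else
        sample(open, length(open), prob = quota[open])
      placed <- FALSE
      for (ci in order_try) {
        cb <- combos[[ci]]
        pick <- character(2)
        feasible <- TRUE
        for (j in 1:2) {
          u <- usage[[cb[j] + 1L]]
          elig <- names(u)[!(names(u) %in% c(recent, pick[1]))]
          if (!length(elig)) { feasible <- FALSE; break }
          umin <- u[elig]
          cand <- names(umin)[umin == min(umin)]
          pick[j] <- if (length(cand) == 1L) cand else sample(cand, 1L)
        }
        if (!feasible) next
        # side assignment: try a random order of the two layouts, take the
        # first that keeps every (side, NWL-count) run at length <= 3
        layouts <- if (runif(1) < 0.5) list(c(1L, 2L), c(2L, 1L)) else
          list(c(2L, 1L), c(1L, 2L))
        for (lay in layouts) {
          cl <- cb[lay[1]]; cr <- cb[lay[2]]
          nl <- if (!is.na(run_val["left"]) && run_val["left"] == cl)
            run_len["left"] + 1L else 1L
          nr <- if (!is.na(run_val["right"]) && run_val["right"] == cr)
            run_len["right"] + 1L else 1L
          if (nl > 3L || nr > 3L) next
          left_img[pos] <- pick[lay[1]]; right_img[pos] <- pick[lay[2]]
          nwl_l[pos] <- cl; nwl_r[pos] <- cr
          combo_ix[pos] <- ci
          run_val["left"] <- cl; run_len["left"] <- nl
          run_val["right"] <- cr; run_len["right"] <- nr
          placed <- TRUE
          break
        }
        if (placed) break
      }
      if (!placed) { ok <- FALSE; break }
      quota[combo_ix[pos]] <- quota[combo_ix[pos]] - 1L
      for (j in 1:2) {
        k <- c(nwl_l[pos], nwl_r[pos])[j] + 1L
        id <- c(left_img[pos], right_img[pos])[j]
        usage[[k]][id] <- usage[[k]][id] + 1L
      }
      prev1 <- if (pos >= 2L) c(left_img[pos - 1L], right_img[pos - 1L])
        else character(0)
      recent <- c(left_img[pos], right_img[pos], prev1)
    }
    if (ok) {
      return(data.frame(
        position = seq_len(n_total), left_image = left_img,
        right_image = right_img, nwl_left = nwl_l, nwl_right = nwl_r,
        combo = vapply(combo_ix, function(ci)
          paste(combos[[ci]], collapse = "v"), character(1)),
        context = inventory$context, stringsAsFactors = FALSE))
    }
  }
  stop(sprintf(paste0(
    "failed to generate a legal sequence after %d restarts; the image ",
    "reuse-gap or side-run constraint is infeasible for this inventory"),
    max_retries), call. = FALSE)
}

#' Audit a pair sequence against the three design rules
#'
#' Independent checker (a plain scan of the sequence, sharing no code with
#' the generator) reporting every violation of the per-combination quota
#' (rule 1), the two-pair image reuse gap (rule 2), and the three-pair
#' same-side NWL-count run limit (rule 3).
#'
#' @param seq_df Sequence data frame as produced by
#'   [generate_pair_sequence()].
#' @param pairs_per_combo Expected pairs per combination; defaults to
#'   `nrow(seq_df) / 6`.
#' @return A `constraint_report`: data frame with columns `rule`, `position`,
#'   `detail` (zero rows when the sequence is clean).
#' @export
validate_sequence <- function(seq_df, pairs_per_combo = nrow(seq_df) / 6) {
  viol <- list()
  add <- function(rule, position, detail)
    viol[[length(viol) + 1L]] <<- data.frame(
      rule = rule, position = position, detail = detail,
      stringsAsFactors = FALSE)

  combo_key <- vapply(seq_len(nrow(seq_df)), function(i)
    paste(sort(c(seq_df$nwl_left[i], seq_df$nwl_right[i])), collapse = "v"),
    character(1))
  expected <- vapply(nwl_combos(), paste, character(1), collapse = "v")
  for (cb in expected) {
    n <- sum(combo_key == cb)
    if (n != pairs_per_combo)
      add("combo_quota", NA_integer_,
          sprintf("combo %s appears %d times, expected %g", cb, n,
                  pairs_per_combo))
  }
  if (any(seq_df$nwl_left == seq_df$nwl_right))
    for (i in which(seq_df$nwl_left == seq_df$nwl_right))
      add("combo_quota", i, "pair with equal NWL counts")

  # rule 2: an image must skip two pairs before reappearing
  for (i in seq_len(nrow(seq_df))) {
    here <- c(seq_df$left_image[i], seq_df$right_image[i])
    if (here[1] == here[2]) add("reuse_gap", i, "same image on both sides")
    back <- max(1L, i - 2L)
    if (i > 1L) {
      prev <- c(seq_df$left_image[back:(i - 1L)],
                seq_df$right_image[back:(i - 1L)])
      hit <- here[here %in% prev]
      for (h in hit)
        add("reuse_gap", i, sprintf("image %s reused within 2 pairs", h))
    }
  }

  # rule 3: same NWL count on the same side for more than 3 consecutive pairs
  for (side in c("left", "right")) {
    counts <- if (side == "left") seq_df$nwl_left else seq_df$nwl_right
    run <- 1L
    for (i in seq_along(counts)[-1]) {
      run <- if (counts[i] == counts[i - 1L]) run + 1L else 1L
      if (run == 4L)  # report the position where the run first exceeds 3
        add("side_run", i,
            sprintf("NWL count %d on %s side for >3 consecutive pairs",
                    counts[i], side))
    }
  }

  out <- if (length(viol)) do.call(rbind, viol) else
    data.frame(rule = character(0), position = integer(0),
               detail = character(0), stringsAsFactors = FALSE)
  class(out) <- c("constraint_report", class(out))
  out
}

#' @export
print.constraint_report <- function(x, ...) {
  if (nrow(x) == 0) cat("Constraint report: clean (no violations)\n")
  else {
    cat(sprintf("Constraint report: %d violation(s)\n", nrow(x)))
    print.data.frame(x)
  }
  invisible(x)
}
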