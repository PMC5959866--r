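# shared fixtures built in code; every random piece takes an explicit seed

quick_inference <- function(seed = 1L, chains = 2, iter = 800, burnin = 500) {
  inference_config(chains = chains, iter = iter, burnin = burnin, seed = seed)
}

# hand-built AP-MS table: one bait, three replicates, three controls.
# bg1/bg2 are ubiquitous background preys; preyX is strongly bait-enriched;
# preyY is flat everywhere.
tiny_apms_table <- function(seed = 42) {
  runs <- c(sprintf("control_%02d", 1:3), sprintf("MLL-AF9_rep%d", 1:3))
  is_ctrl <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  mean_counts <- rbind(
    bg1   = c(30, 30, 30, 30, 30, 30),
    bg2   = c(25, 25, 25, 25, 25, 25),
    preyX = c(1, 0, 1, 20, 22, 18),
    preyY = c(5, 5, 5, 5, 5, 5)
  )
  withr_seed <- function(code) { set.seed(seed); code }
  rows <- list()
  for (p in rownames(mean_counts)) {
    for (r in seq_along(runs)) {
      cnt <- mean_counts[p, r]
      rows[[length(rows) + 1]] <- tibble::tibble(
        bait_id = ifelse(is_ctrl[r], NA_character_, "MLL-AF9"),
        run_id = runs[r], is_control = is_ctrl[r], prey_id = p,
        spectral_count = cnt,
        score_a = ifelse(cnt > 0, cnt * 8, NA_real_),
        score_b = ifelse(cnt > 0, cnt * 10, NA_real_)
      )
    }
  }
  dplyr::bind_rows(rows)
}

tiny_apms_dataset <- function(...) {
  preprocess_apms(tiny_apms_table(...),
                  background_prey_ids = c("bg1", "bg2"))
}

# independent partition enumeration for the community-detection oracle:
# canonicalize all n^n labelings by first-appearance relabelling
all_partitions_bruteforce <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  canon <- apply(grid, 1, function(lab) {
    first <- match(unique(lab), lab)
    relab <- match(lab, lab[sort(first)])
    paste(relab, collapse = ",")
  })
  unique_str <- unique(canon)
  lapply(strsplit(unique_str, ","), as.integer)
}

# deterministic small graph helpers
two_triangles <- function() {
  tibble::tibble(a = c("a1", "a2", "a1", "b1", "b2", "b1"),
                 b = c("a2", "a3", "a3", "b2", "b3", "b3"))
}

three_cliques <- function() {
  cl <- function(prefix) {
    nodes <- paste0(prefix, 1:4)
    cp <- utils::combn(nodes, 2)
    tibble::tibble(a = cp[1, ], b = cp[2, ])
  }
  dplyr::bind_rows(cl("x"), cl("y"), cl("z"),
                   tibble::tibble(a = c("x1", "y1"), b = c("y1", "z1")))
}
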