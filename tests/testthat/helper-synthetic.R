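# Shared fixtures, built in code. The compact 25 x 128 grid keeps the same
# B-scan count and field of view as the full protocol while making per-test
# simulation cheap.

tiny_geom <- function() oct_geometry(n_ascans = 128L)

# memoized default template on the compact grid
.tiny_template_cache <- new.env(parent = emptyenv())
tiny_template <- function() {
  if (is.null(.tiny_template_cache$tpl))
    .tiny_template_cache$tpl <- make_template(template_spec(geometry = tiny_geom()))
  .tiny_template_cache$tpl
}

tiny_target <- function() {
  if (is.null(.tiny_template_cache$tg))
    .tiny_template_cache$tg <- build_target(list(tiny_template()),
                                            policy = "designated-reference")
  .tiny_template_cache$tg
}

# a small flat thickness map for unit tests
flat_map <- function(value = 100, layer = "GCIPL", laterality = "L",
                     geom = oct_geometry(n_bscans = 10L, n_ascans = 16L),
                     registered = FALSE, subject_id = "S1") {
  thickness_map(matrix(value, geom$n_bscans, geom$n_ascans), layer,
                laterality, geom, registered = registered,
                subject_id = subject_id)
}

# build a registered group stack directly from a subject x row x col array
stack_from_array <- function(data, cov, layer = "GCIPL",
                             geom = NULL) {
  R <- dim(data)[2]; C <- dim(data)[3]
  if (is.null(geom)) geom <- oct_geometry(n_bscans = R, n_ascans = C)
  maps <- lapply(seq_len(dim(data)[1]), function(i)
    thickness_map(data[i, , ], layer, "L", geom, registered = TRUE,
                  subject_id = cov$subject_id[i]))
  build_group_stack(maps, cov)
}

random_cov <- function(n, groups = c("HC", "RMS")) {
  data.frame(subject_id = sprintf("S%03d", seq_len(n)), eye = "OS",
             group = rep(groups, length.out = n),
             age = runif(n, 20, 60), sex = sample(c("M", "F"), n, TRUE),
             edss = round(runif(n, 0, 6) * 2) / 2,
             disease_duration = rexp(n, 1 / 4))
}

# independent flood-fill connected components (oracle for cluster_filter)
flood_fill_components <- function(sig, connectivity = 8L) {
  R <- nrow(sig); C <- ncol(sig)
  lab <- matrix(0L, R, C)
  cur <- 0L
  offs <- if (connectivity == 4L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  for (r in seq_len(R)) for (cc in seq_len(C)) {
    if (!sig[r, cc] || lab[r, cc] > 0L) next
    cur <- cur + 1L
    queue <- list(c(r, cc))
    lab[r, cc] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        q <- p + o
        if (q[1] >= 1 && q[1] <= R && q[2] >= 1 && q[2] <= C &&
            sig[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}
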