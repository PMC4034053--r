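# Shared, lazily computed expensive objects (full network runs take a
# couple of seconds each); cached across test files within one session.
.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .run_cache, inherits = FALSE))
    assign(name, force(expr), envir = .run_cache)
  get(name, envir = .run_cache, inherits = FALSE)
}

default_config_cached <- function() cached("config", network_config())

fixtures_cached <- function() cached("fixtures", default_fixtures())

member_run <- function(set_name, transform) {
  cached(paste0(set_name, "_", transform), {
    fx <- fixtures_cached()
    run_network(fx[[set_name]][[transform]], default_config_cached())
  })
}

set_report <- function(set_name) {
  cached(paste0("report_", set_name), {
    # assemble the report from the cached member runs instead of re-running
    fx <- fixtures_cached()
    transforms <- c("original", "mirror", "contrast", "fg")
    runs <- lapply(transforms, function(tr) member_run(set_name, tr))
    names(runs) <- transforms
    per <- lapply(runs, fgspike:::summarize_run)
    structure(list(label = fx[[set_name]]$label, transforms = per,
                   flags = fgspike:::fg_flags(per),
                   config_hash = config_hash(default_config_cached()),
                   runs = NULL),
              class = "experiment_report")
  })
}

circle_report_cached <- function() {
  cached("circle_report", run_circle_experiment(default_config_cached()))
}

rotation_run <- function() {
  cached("rot90_set1", {
    fx <- fixtures_cached()
    run_network(rotate90(fx$set1$original), default_config_cached())
  })
}

# small framed stimulus for cheap structural network tests
small_stimulus <- function() {
  cached("small_stimulus", {
    n <- 16L; m <- 4L
    p <- rep(8L, n); p[4:12] <- 6L; p[1L] <- 8L; p[n] <- 8L
    generate_polygon_stimulus(profile_spec(p, "left"), n, m,
                              label = "small")
  })
}

short_config <- function(duration = 40) {
  network_config(duration = duration)
}
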