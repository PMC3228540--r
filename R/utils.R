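# Evaluate expr under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = env, inherits = FALSE)
        on.exit(assign(".Random.seed", old, envir = env))
    } else {
        on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env))
    }
    set.seed(seed)
    expr
}
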