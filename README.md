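# riboclear

Recovery of ribosome A-site position signals from ribosome profiling data.

## The problem

Ribosome profiling ("ribo-seq") reads are mRNA fragments protected by
translating ribosomes. Codon-level analyses — decoding speed, pausing,
frameshift detection — need to know which codon sat in the ribosomal A site
for each read. Imperfect RNase digestion scatters read 5' ends over a range
of lengths and offsets, so fixed-offset A-site rules (+15 nt from the 5'
end, or one offset per read length) misassign a large fraction of reads and
wash out the 3-nt periodicity of the signal.

`riboclear` treats the observed length-stratified 5'-end pileup
`P_obs(l)` of a transcript as a convolution of a hidden, length-independent
position signal `P_true` with a per-length digestion blur vector `b(l)`:

    P_obs(l) = b(l) * ( shift(P_true, -(l - 28)) - eps(l) ) + noise

The blur vectors (relocation probabilities over offsets −15…+15) are
estimated from start-codon-anchored meta-profiles by non-negative least
squares inside an EM-like loop. Each transcript is then deconvolved by an
EM-like ridge-regularized total-least-squares procedure (exact banded
M-step for the deviations `eps(l)`, weighted-average E-step with clipping
and renormalization for the consensus), and the recovered length-specific
signals are merged into a sub-codon A-site profile using the per-length
offset `l − 13`. Downstream, per-codon decoding times are estimated as the
skewness of lognormal fits to normalized codon counts, including
Watson–Crick vs wobble comparisons within same-tRNA codon pairs.

A seeded synthetic generator (frame-0 consensus signals with a 5'
translational ramp, unimodal blur kernels, multinomial read sampling,
optional planted frameshifts and codon dwell structure) provides
ground-truth recovery tests for every stage. See
`vignettes/deblur-methods.Rmd` for the model, parameter and design notes.

## Worked example

```r
library(riboclear)

# simulate a small deep-coverage yeast-like data set
spec <- synthetic_spec(n_transcripts = 20, depth = 10000, seed = 42)
truth <- generate_truth(spec)
profiles <- sample_reads(truth)

# estimate per-length digestion blur vectors from meta-profiles
metas <- lapply(spec$read_lengths, function(l)
  build_meta_profile(profiles, l, truth$annotations))
fit <- estimate_all_blurs(metas)
fit$blurs[["30"]]
#> <blur_vector> l=30  mode_offset=+0  mass(sum)=1.0000

# deconvolve one transcript and merge the A-site profile
sets <- filter_profiles(profiles, truth$annotations)
res <- deblur_transcript(sets[[1]], fit$blurs)
res
#> <deblur_result> TX0001  lengths={26,27,28,29,30}  iters=4  converged=TRUE
asite <- merge_asite(res)

# frame skewness: naive +15-offset assignment vs deblurred
naive <- Reduce(`+`, lapply(sets[[1]]$profiles,
                            function(p) shift_profile(p$counts, 15)))
round(rbind(
  naive  = frame_fractions(list(values = naive, start = asite$start)),
  deblur = frame_fractions(asite)), 3)
#>         [,1]  [,2]  [,3]
#> naive  0.494 0.247 0.259
#> deblur 0.921 0.039 0.040

# recovered consensus vs planted truth
round(cor(res$consensus, truth$transcripts[[res$transcript_id]]$consensus), 3)
#> [1] 0.98
```

The three columns are the fractions of A-site mass in frames 0/1/2 relative
to the start codon. Mixing five read lengths with a naive +15 offset leaves
barely half of the mass in frame (0.494); after deconvolution 92% of the
mass is on frame 0, and the recovered consensus correlates at r = 0.98 with
the planted truth.

## Command line

```sh
exec/riboclear simulate        --out fixture --sam
exec/riboclear build-profiles  --bam fixture/reads.sam --annot fixture/annotation.tsv --out profiles.tsv
exec/riboclear estimate-blur   --profiles profiles.tsv --annot fixture/annotation.tsv --out blur.tsv
exec/riboclear deblur          --profiles profiles.tsv --annot fixture/annotation.tsv --blur blur.tsv --out deblurred.tsv
exec/riboclear asite           --deblurred deblurred.tsv --profiles profiles.tsv --annot fixture/annotation.tsv --out asite.tsv
exec/riboclear cdt             --asite asite.tsv --annot fixture/annotation.tsv --fasta fixture/cds.fa --out cdt.tsv
```

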