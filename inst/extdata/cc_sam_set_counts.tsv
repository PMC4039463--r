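# SAM differential-expression set sizes for the cervical carcinoma cohort:
# tumors grouped by %CN-altered genome (high, n=10; low, n=11-group analog n per text),
# each group compared against the 17 controls; counts of called genes and, for the
# exclusive-high set, its copy-number recurrence strata across the 10 high-CN tumors.
key	value
n_deregulated_high	1757
n_deregulated_low	1104
n_common	895
exclusive_high_altered_ge6	79
exclusive_high_altered_4to5	118
exclusive_high_altered_1to3	370
exclusive_high_altered_0	295
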