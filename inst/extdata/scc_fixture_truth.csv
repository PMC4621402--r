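subject_id,true_disposition,true_shape
S001,integrated_functional,discontinuous_other
S002,integrated_functional,discontinuous_other
S003,integrated_functional,monotonic_decrease
S004,integrated_functional,monotonic_decrease
S005,integrated_functional,monotonic_decrease
S006,integrated_functional,v_shape
S007,integrated_dysfunctional,v_shape
S008,integrated_dysfunctional,v_shape
S009,integrated_dysfunctional,plateau
S010,integrated_dysfunctional,plateau
S011,integrated_dysfunctional,discontinuous_other
S012,integrated_dysfunctional,discontinuous_other
S013,disintegrated_functional,discontinuous_other
S014,disintegrated_functional,v_shape
S015,disintegrated_functional,monotonic_decrease
S016,disintegrated_functional,plateau
S017,disintegrated_functional,monotonic_decrease
S018,disintegrated_functional,discontinuous_other
S019,disintegrated_dysfunctional,discontinuous_other
S020,disintegrated_dysfunctional,discontinuous_other
S021,disintegrated_dysfunctional,v_shape
S022,disintegrated_dysfunctional,discontinuous_other
S023,disintegrated_dysfunctional,monotonic_increase
S024,disintegrated_dysfunctional,monotonic_decrease
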