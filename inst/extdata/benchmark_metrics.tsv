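method	accuracy	sensitivity	specificity	npv	ppv	auc
BitSeq	0.9442	0.5233	0.9984	0.942	0.9771	0.7609
EBSeq	0.9901	0.9733	0.9923	0.9965	0.9421	0.9828
Hisat	0.9472	0.9511	0.9466	0.9934	0.6967	0.9489
XGBoost	0.9928	0.9980	0.9522	0.9837	0.9939	0.9838
RF	0.9807	0.9803	0.9844	0.9845	0.9793	0.9793
RSEM	0.9884	0.9281	0.9961	0.9908	0.9687	0.9621
RTF	0.9807	0.9779	0.9836	0.9831	0.9768	0.9768
Sleuth	0.931	0.5543	0.9795	0.9446	0.7769	0.7669
SVM	0.9782	0.9777	0.9843	0.9832	0.9771	0.9766
TopHat	0.9773	0.9336	0.9829	0.9914	0.8754	0.9582
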