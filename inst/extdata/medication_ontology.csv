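medication,class
vigabatrin,GABAergic
clobazam,GABAergic
phenobarbital,GABAergic
clonazepam,GABAergic
diazepam,GABAergic
oxcarbazepine,non-GABAergic
levetiracetam,non-GABAergic
lamotrigine,non-GABAergic
topiramate,non-GABAergic
zonisamide,non-GABAergic
ethosuximide,non-GABAergic
valproate,non-GABAergic
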