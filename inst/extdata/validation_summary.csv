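sample,deletion_attempted,deletion_non_validated,deletion_constitutional,deletion_somatic,inversion_attempted,inversion_non_validated,inversion_constitutional,inversion_somatic,translocation_attempted,translocation_non_validated,translocation_constitutional,translocation_somatic
113T,8,8,0,0,0,0,0,0,2,2,0,0
114T,5,4,1,0,0,0,0,0,5,2,3,0
116T,1,0,1,0,4,2,0,2,1,0,0,1
117T,0,0,0,0,0,0,0,0,1,0,1,0
118T,3,1,2,0,0,0,0,0,12,5,1,6
119T,1,0,0,1,3,3,0,0,3,0,0,3
120T,3,0,3,0,3,2,0,1,3,0,0,3
147T,2,0,2,0,0,0,0,0,0,0,0,0
148T,4,0,4,0,5,5,0,0,8,3,3,2
149T,16,4,8,4,1,0,0,1,9,4,1,4
150T,5,1,4,0,1,1,0,0,0,0,0,0
151T,4,0,4,0,1,0,0,1,1,1,0,0
152T,1,0,0,1,0,0,0,0,0,0,0,0
153T,19,9,9,1,6,3,3,0,12,3,3,6
154T,7,1,5,1,1,0,0,1,4,1,2,1
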